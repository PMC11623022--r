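name,x,y,z
Fp1,0.951056516295154,0.154508497187474,0.267616567329817
Fpz,0.951056516295154,0,0.309016994374947
Fp2,0.951056516295154,-0.154508497187474,0.267616567329817
AF7,0.809016994374947,0.55233746418602,0.201034396233786
AF3,0.809016994374947,0.337139770349617,0.4814854910183
AFz,0.809016994374947,0,0.587785252292473
AF4,0.809016994374947,-0.337139770349617,0.4814854910183
AF8,0.809016994374947,-0.55233746418602,0.201034396233786
F7,0.587785252292473,0.809016994374947,4.95380036308546e-17
F5,0.587785252292473,0.747434242556813,0.309597400249093
F3,0.587785252292473,0.572061402817684,0.572061402817684
F1,0.587785252292473,0.309597400249093,0.747434242556813
Fz,0.587785252292473,0,0.809016994374947
F2,0.587785252292473,-0.309597400249093,0.747434242556813
F4,0.587785252292473,-0.572061402817684,0.572061402817684
F6,0.587785252292473,-0.747434242556813,0.309597400249093
F8,0.587785252292473,-0.809016994374947,4.95380036308546e-17
FT7,0.309016994374948,0.951056516295154,5.82354159244546e-17
FC5,0.309016994374947,0.878661649666579,0.363953572029014
FC3,0.309016994374947,0.672498511963957,0.672498511963957
FC1,0.309016994374947,0.363953572029014,0.878661649666579
FCz,0.309016994374948,0,0.951056516295154
FC2,0.309016994374947,-0.363953572029014,0.878661649666579
FC4,0.309016994374947,-0.672498511963957,0.672498511963957
FC6,0.309016994374947,-0.878661649666579,0.363953572029014
FT8,0.309016994374948,-0.951056516295154,5.82354159244546e-17
T7,6.12323399573677e-17,1,6.12323399573677e-17
C5,6.12323399573677e-17,0.923879532511287,0.38268343236509
C3,6.12323399573677e-17,0.707106781186547,0.707106781186548
C1,6.12323399573677e-17,0.38268343236509,0.923879532511287
Cz,6.12323399573677e-17,0,1
C2,6.12323399573677e-17,-0.38268343236509,0.923879532511287
C4,6.12323399573677e-17,-0.707106781186547,0.707106781186548
C6,6.12323399573677e-17,-0.923879532511287,0.38268343236509
T8,6.12323399573677e-17,-1,6.12323399573677e-17
TP7,-0.309016994374947,0.951056516295154,5.82354159244546e-17
CP5,-0.309016994374947,0.87866164966658,0.363953572029014
CP3,-0.309016994374947,0.672498511963957,0.672498511963957
CP1,-0.309016994374947,0.363953572029014,0.87866164966658
CPz,-0.309016994374947,0,0.951056516295154
CP2,-0.309016994374947,-0.363953572029014,0.87866164966658
CP4,-0.309016994374947,-0.672498511963957,0.672498511963957
CP6,-0.309016994374947,-0.87866164966658,0.363953572029014
TP8,-0.309016994374947,-0.951056516295154,5.82354159244546e-17
P9,-0.587785252292473,0.747434242556813,-0.309597400249093
P7,-0.587785252292473,0.809016994374948,4.95380036308546e-17
P5,-0.587785252292473,0.747434242556813,0.309597400249093
P3,-0.587785252292473,0.572061402817684,0.572061402817684
P1,-0.587785252292473,0.309597400249093,0.747434242556813
Pz,-0.587785252292473,0,0.809016994374948
P2,-0.587785252292473,-0.309597400249093,0.747434242556813
P4,-0.587785252292473,-0.572061402817684,0.572061402817684
P6,-0.587785252292473,-0.747434242556813,0.309597400249093
P8,-0.587785252292473,-0.809016994374948,4.95380036308546e-17
P10,-0.587785252292473,-0.747434242556813,-0.309597400249093
PO7,-0.809016994374947,0.55233746418602,0.201034396233786
PO3,-0.809016994374947,0.337139770349617,0.4814854910183
POz,-0.809016994374947,0,0.587785252292473
PO4,-0.809016994374947,-0.337139770349617,0.4814854910183
PO8,-0.809016994374947,-0.55233746418602,0.201034396233786
O1,-0.951056516295154,0.154508497187474,0.267616567329818
Oz,-0.951056516295154,0,0.309016994374948
O2,-0.951056516295154,-0.154508497187474,0.267616567329818
Iz,-1,0,1.22464679914735e-16
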