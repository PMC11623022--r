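#' Generator architecture specification
#'
#' The generator maps a 100-dimensional latent vector, conditioned on the
#' class label by an elementwise learned embedding, through
#' FC -> BN -> ReLU -> reshape 7x7x256 -> dropout ->
#' tconv 5x5 256->128 -> BN -> ReLU -> upsample -> tconv 3x3 128->64 -> BN ->
#' ReLU -> upsample -> tconv 3x3 64->32 -> BN -> ReLU -> tconv 3x3 32->1 ->
#' tanh, producing 28x28x1 images in (-1, 1). At `width_scale = 1` the
#' per-layer parameter counts reproduce the reference architecture table
#' exactly (FC 1,266,944; BN 50,176; transposed convolutions 819,328 /
#' 73,792 / 18,464 / 289). Kernel sizes (5x5 then 3x3) and the latent
#' dimension are the unique solutions of the printed parameter counts.
#'
#' @param latent_dim latent dimension (100).
#' @param width_scale multiplies all channel widths; < 1 gives a cheap model
#'   for smoke tests (parameter-count checks then no longer apply).
#' @param dropout generator dropout rate.
#' @param n_classes number of label classes (left/right).
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(latent_dim = 100L, width_scale = 1,
                           dropout = 0.4, n_classes = 2L) {
  ch <- function(x) max(1L, as.integer(round(x * width_scale)))
  structure(list(latent_dim = as.integer(latent_dim),
                 channels = c(ch(256), ch(128), ch(64), ch(32)),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 width_scale = width_scale),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Shared trunk conv 3x3 stride 2 (1->64) -> LeakyReLU -> dropout ->
#' conv 3x3 s2 (64->128) -> conv 3x3 s2 (128->256) -> conv 3x3 s1
#' (256->512) -> flatten (8192), then two heads: source FC->1 sigmoid
#' (real/generated) and auxiliary class FC->2 softmax (left/right). At
#' `width_scale = 1` trunk and source-head parameter counts reproduce the
#' reference table (640 / 73,856 / 295,168 / 1,180,160 / 8,193). The
#' auxiliary head is reconstructed from the text (the printed table omits
#' it); no batch norm, matching the table.
#'
#' @param width_scale channel-width multiplier.
#' @param dropout discriminator dropout rate.
#' @param leaky_slope LeakyReLU negative slope.
#' @param n_classes number of label classes.
#' @return A `discriminator_spec` object.
#' @export
discriminator_spec <- function(width_scale = 1, dropout = 0.25,
                               leaky_slope = 0.2, n_classes = 2L) {
  ch <- function(x) max(1L, as.integer(round(x * width_scale)))
  structure(list(channels = c(ch(64), ch(128), ch(256), ch(512)),
                 dropout = dropout, leaky_slope = leaky_slope,
                 n_classes = as.integer(n_classes),
                 width_scale = width_scale),
            class = "discriminator_spec")
}

#' Build the generator network
#'
#' @param spec a [generator_spec()].
#' @return A model list with layers, the label embedding, and metadata.
#' @export
build_generator <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  ch <- spec$channels
  fc_out <- 7L * 7L * ch[1]
  layers <- list(
    layer_dense(spec$latent_dim, fc_out, name = "FC"),
    layer_batchnorm(fc_out, name = "BN"),
    layer_activation("relu", name = "Activation(ReLU)"),
    layer_reshape(c(7L, 7L, ch[1]), name = "Reshape"),
    layer_dropout(spec$dropout, name = "Dropout"),
    layer_conv(ch[1], ch[2], 5L, 1L, name = "Conv2D Transpose"),
    layer_batchnorm(ch[2], name = "BN"),
    layer_activation("relu", name = "Activation(ReLU)"),
    layer_upsample(name = "UpSampling2D"),
    layer_conv(ch[2], ch[3], 3L, 1L, name = "Conv2D Transpose"),
    layer_batchnorm(ch[3], name = "BN"),
    layer_activation("relu", name = "Activation(ReLU)"),
    layer_upsample(name = "UpSampling2D"),
    layer_conv(ch[3], ch[4], 3L, 1L, name = "Conv2D Transpose"),
    layer_batchnorm(ch[4], name = "BN"),
    layer_activation("relu", name = "Activation(ReLU)"),
    layer_conv(ch[4], 1L, 3L, 1L, name = "Conv2D Transpose"),
    layer_activation("tanh", name = "Activation(tanh)"))
  embedding <- new_layer("embedding", name = "LabelEmbedding")
  # deterministic anti-symmetric init around 1: class signatures differ in
  # every latent dimension from the start, so the auxiliary head has an
  # immediate gradient to latch onto (identity-like inits stall class
  # conditioning at small training scales)
  sgn <- rep_len(c(1, -1), spec$latent_dim)
  embedding$params$E <- rbind(1 + 0.5 * sgn, 1 - 0.5 * sgn)
  if (spec$n_classes != 2L)
    embedding$params$E <- matrix(1 + 0.5 * stats::rnorm(spec$n_classes *
                                                          spec$latent_dim),
                                 spec$n_classes, spec$latent_dim)
  list(kind = "generator", spec = spec, layers = layers,
       embedding = embedding, classes = c("left", "right"))
}

#' Build the discriminator network
#'
#' @param spec a [discriminator_spec()].
#' @return A model list with trunk layers and the two heads.
#' @export
build_discriminator <- function(spec = discriminator_spec()) {
  stopifnot(inherits(spec, "discriminator_spec"))
  ch <- spec$channels
  trunk <- list(
    layer_conv(1L, ch[1], 3L, 2L, name = "Conv2D"),
    layer_activation("lrelu", spec$leaky_slope, name = "LeakyReLU"),
    layer_dropout(spec$dropout, name = "Dropout"),
    layer_conv(ch[1], ch[2], 3L, 2L, name = "Conv2D"),
    layer_activation("lrelu", spec$leaky_slope, name = "LeakyReLU"),
    layer_dropout(spec$dropout, name = "Dropout"),
    layer_conv(ch[2], ch[3], 3L, 2L, name = "Conv2D"),
    layer_activation("lrelu", spec$leaky_slope, name = "LeakyReLU"),
    layer_dropout(spec$dropout, name = "Dropout"),
    layer_conv(ch[3], ch[4], 3L, 1L, name = "Conv2D"),
    layer_activation("lrelu", spec$leaky_slope, name = "LeakyReLU"),
    layer_dropout(spec$dropout, name = "Dropout"),
    layer_flatten(name = "Flatten"))
  feat <- 4L * 4L * ch[4]
  source_head <- layer_dense(feat, 1L, name = "FC(sigmoid)")
  class_head <- layer_dense(feat, spec$n_classes, name = "FC(softmax)")
  list(kind = "discriminator", spec = spec, trunk = trunk,
       source_head = source_head, class_head = class_head,
       classes = c("left", "right"))
}

#' Per-layer parameter counts of a model
#'
#' Counts trainable plus non-trainable (batch-norm moving statistics)
#' parameters per layer, the way framework model summaries print them, so the
#' counts are directly comparable with the reference architecture table.
#'
#' @param model a built generator or discriminator.
#' @param include_class_head for discriminators, include the auxiliary class
#'   head (not part of the printed table; default FALSE).
#' @return `data.frame` with `layer` and `params` columns.
#' @export
count_params <- function(model, include_class_head = FALSE) {
  layers <- if (model$kind == "generator") model$layers
            else c(model$trunk, list(model$source_head),
                   if (include_class_head) list(model$class_head))
  data.frame(layer = vapply(layers, function(l) l$name, character(1)),
             params = vapply(layers, layer_param_count, numeric(1)))
}

#' Sample and condition latent vectors
#'
#' Latent vectors are drawn i.i.d. uniform(-1, 1); conditioning multiplies
#' the latent vector elementwise by a learned 100-dimensional label
#' embedding, which keeps the generator FC input at 100 dimensions
#' (concatenation would contradict the printed FC parameter count
#' 12544 x 101).
#'
#' @param model a built generator.
#' @param n number of samples.
#' @param labels character vector (recycled) of `"left"` / `"right"`.
#' @return List with `z` (latent_dim x n), `zc` (conditioned), `labels`.
#' @export
sample_latent <- function(model, n, labels) {
  d <- model$spec$latent_dim
  labels <- rep_len(labels, n)
  z <- matrix(stats::runif(d * n, -1, 1), d, n)
  list(z = z, zc = condition_latent(model, z, labels), labels = labels)
}

#' @rdname sample_latent
#' @param z latent matrix (latent_dim x n).
#' @export
condition_latent <- function(model, z, labels) {
  idx <- match(labels, model$classes)
  if (anyNA(idx)) stop("unknown label(s): ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "))
  z * t(model$embedding$params$E[idx, , drop = FALSE])
}

#' Generator forward pass
#'
#' @param model a built generator.
#' @param zc conditioned latent matrix (latent_dim x n).
#' @param training training mode (batch-norm batch statistics, dropout on).
#' @return Array `28 x 28 x 1 x n` of values in `(-1, 1)`.
#' @export
generator_forward <- function(model, zc, training = FALSE) {
  # with use_batch_stats = TRUE in both modes: at the small training scales
  # this package targets, batch-norm moving averages lag far behind the
  # batch statistics the network was actually trained with.
  layers_forward(model$layers, zc, training = training,
                 use_batch_stats = TRUE)
}

#' Discriminator forward pass
#'
#' @param model a built discriminator.
#' @param x image array `28 x 28 x 1 x n` (a single map is promoted).
#' @param training training mode (dropout on).
#' @return List with `source` (probability real, length n), `class_probs`
#'   (n_classes x n softmax), plus the head logits.
#' @export
discriminator_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L, 1L)
  feat <- layers_forward(model$trunk, x, training = training)
  s_logit <- dense_forward(model$source_head, feat, training)
  c_logit <- dense_forward(model$class_head, feat, training)
  cp <- softmax_cols(c_logit)
  list(source = as.numeric(1 / (1 + exp(-s_logit))), class_probs = cp,
       s_logit = s_logit, c_logit = c_logit, features = feat)
}

softmax_cols <- function(m) {
  m <- exp(m - rep(apply(m, 2, max), each = nrow(m)))
  m / rep(colSums(m), each = nrow(m))
}

# probability clamp used by both losses
.eps_clamp <- 1e-7
clamp01 <- function(p) pmin(pmax(p, .eps_clamp), 1 - .eps_clamp)

#' Adversarial source loss
#'
#' Negated source log-likelihood, minimized by the discriminator:
#' `-(mean(log p_real) + mean(log(1 - p_fake)))`. Non-negative after
#' probability clamping; 0 only at perfect discrimination.
#'
#' @param real_probs discriminator source probabilities on real images.
#' @param fake_probs source probabilities on generated images.
#' @return Scalar loss.
#' @export
source_loss <- function(real_probs, fake_probs) {
  -(mean(log(clamp01(real_probs))) + mean(log(1 - clamp01(fake_probs))))
}

#' Auxiliary classification loss
#'
#' Negated class log-likelihood (cross-entropy) over a batch:
#' `-mean(log p(class = c | x))`. Real and generated batches each contribute
#' one such term during training.
#'
#' @param class_probs n_classes x n matrix of class probabilities.
#' @param true_labels character labels or integer class indices.
#' @param classes class name order for character labels.
#' @return Scalar loss.
#' @export
class_loss <- function(class_probs, true_labels,
                       classes = c("left", "right")) {
  idx <- if (is.character(true_labels)) match(true_labels, classes)
         else as.integer(true_labels)
  if (anyNA(idx)) stop("unknown label in class_loss")
  p <- class_probs[cbind(idx, seq_along(idx))]
  -mean(log(clamp01(p)))
}

#' Training configuration
#'
#' Defaults follow the best-performing printed hyperparameter row: generator
#' learning rate 2e-4, discriminator 1e-4, batch size 8, 200 epochs, ADAM
#' (beta1 = 0.5 by GAN convention, beta2 = 0.999).
#'
#' @param lr_generator,lr_discriminator ADAM learning rates.
#' @param batch_size minibatch size (the text elsewhere mentions 32; 8 is the
#'   printed best row and the default).
#' @param epochs training epochs.
#' @param beta1,beta2 ADAM moment decay rates.
#' @param seed RNG seed for reproducible training, or NULL.
#' @param width_scale channel-width multiplier for both networks.
#' @param dropout_g,dropout_d dropout rates.
#' @return A `train_config` object.
#' @export
train_config <- function(lr_generator = 2e-4, lr_discriminator = 1e-4,
                         batch_size = 8L, epochs = 200L,
                         beta1 = 0.5, beta2 = 0.999, seed = NULL,
                         width_scale = 1, dropout_g = 0.4, dropout_d = 0.25) {
  stopifnot(lr_generator > 0, lr_discriminator > 0, batch_size >= 1,
            epochs >= 1)
  structure(list(lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 seed = seed, width_scale = width_scale,
                 dropout_g = dropout_g, dropout_d = dropout_d),
            class = "train_config")
}

maps_to_batch_array <- function(maps, idx) {
  gn <- nrow(maps[[1]]$grid)
  x <- array(0, c(gn, gn, 1L, length(idx)))
  for (j in seq_along(idx)) x[, , 1L, j] <- maps[[idx[j]]]$grid
  x
}

# Backward pass of the discriminator loss given head-derivative matrices;
# returns gradient wrt the input images and fills layer grads.
discriminator_backward <- function(model, ds_logit, dc_logit) {
  dfeat <- dense_backward(model$source_head, ds_logit) +
    dense_backward(model$class_head, dc_logit)
  layers_backward(model$trunk, dfeat)
}

#' Train the auxiliary-classifier GAN
#'
#' Alternating minibatch updates per the three-step scheme: (1) the generator
#' produces a fake batch from noise and sampled labels; (2) fakes and a real
#' batch are presented to the discriminator; (3) the discriminator is updated
#' to minimize `L_source + L_class` (negated log-likelihoods) with the
#' generator frozen, then the generator is updated to minimize
#' `L_source - L_class` restricted to its own terms (equivalently, to
#' maximize `L_class - L_source`) with the discriminator frozen. Losses are
#' logged per epoch; any non-finite loss aborts with a diagnostic.
#'
#' @param maps list of [ssf_map()]s, normalized to `[-1, 1]`, with labels;
#'   at least 2 per class.
#' @param config a [train_config()].
#' @return List with `generator`, `discriminator`, `history` (data.frame of
#'   per-epoch mean `L_source_D`, `L_class_D`, `L_source_G`, `L_class_G`)
#'   and `config`.
#' @export
train_adgan <- function(maps, config = train_config()) {
  labels <- ssf_labels(maps)
  if (anyNA(labels)) stop("all maps must be labeled for GAN training")
  if (min(table(factor(labels, levels = c("left", "right")))) < 2)
    stop("need at least 2 maps per class")
  if (!is.null(config$seed)) set.seed(config$seed)
  gen <- build_generator(generator_spec(width_scale = config$width_scale,
                                        dropout = config$dropout_g))
  disc <- build_discriminator(discriminator_spec(
    width_scale = config$width_scale, dropout = config$dropout_d))
  opt_g <- adam_state(config$lr_generator, config$beta1, config$beta2)
  opt_d <- adam_state(config$lr_discriminator, config$beta1, config$beta2)
  g_layers <- c(gen$layers, list(gen$embedding))
  d_layers <- c(disc$trunk, list(disc$source_head, disc$class_head))
  n <- length(maps); B <- min(config$batch_size, n)
  classes <- disc$classes
  hist <- matrix(NA_real_, config$epochs, 4,
                 dimnames = list(NULL, c("L_source_D", "L_class_D",
                                         "L_source_G", "L_class_G")))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    acc <- matrix(0, 0, 4)
    for (start in seq(1L, n - B + 1L, by = B)) {
      ridx <- ord[start:(start + B - 1L)]
      x_real <- maps_to_batch_array(maps, ridx)
      y_real <- labels[ridx]
      # -- step 1: fake batch from noise and sampled labels
      lat <- sample_latent(gen, B, sample(classes, B, replace = TRUE))
      x_fake <- generator_forward(gen, lat$zc, training = TRUE)
      # -- step 2+3: discriminator update, generator frozen
      out_r <- discriminator_forward(disc, x_real, training = TRUE)
      dsr <- matrix(-(1 - out_r$source) / B, 1)          # d/ds_logit BCE(1)
      ohr <- onehot(y_real, classes)
      dcr <- (out_r$class_probs - ohr) / B
      d_in_r <- discriminator_backward(disc, dsr, dcr)
      grads_r <- collect_grads(d_layers)
      out_f <- discriminator_forward(disc, x_fake, training = TRUE)
      dsf <- matrix(out_f$source / B, 1)                 # d/ds_logit BCE(0)
      ohf <- onehot(lat$labels, classes)
      dcf <- (out_f$class_probs - ohf) / B
      discriminator_backward(disc, dsf, dcf)
      add_grads(d_layers, grads_r)
      opt_d <- adam_update(d_layers, opt_d)
      Ls_d <- source_loss(out_r$source, out_f$source)
      Lc_d <- class_loss(out_r$class_probs, y_real) +
        class_loss(out_f$class_probs, lat$labels)
      # -- generator update, discriminator frozen
      lat2 <- sample_latent(gen, B, sample(classes, B, replace = TRUE))
      x_g <- generator_forward(gen, lat2$zc, training = TRUE)
      out_g <- discriminator_forward(disc, x_g, training = TRUE)
      # J_G = mean log(1 - p_fake) + class CE on fakes
      dsg <- matrix(-out_g$source / B, 1)
      ohg <- onehot(lat2$labels, classes)
      dcg <- (out_g$class_probs - ohg) / B
      dx_g <- discriminator_backward(disc, dsg, dcg)
      dzc <- layers_backward(gen$layers, dx_g)
      gen$embedding$grads$E <- embedding_grad(gen, lat2, dzc)
      opt_g <- adam_update(g_layers, opt_g)
      Ls_g <- mean(log(1 - clamp01(out_g$source))) * -1  # report as positive CE
      Lc_g <- class_loss(out_g$class_probs, lat2$labels)
      row <- c(Ls_d, Lc_d, Ls_g, Lc_g)
      if (any(!is.finite(row)))
        stop(sprintf("non-finite loss at epoch %d (%s)", ep,
                     paste(signif(row, 4), collapse = ", ")))
      acc <- rbind(acc, row)
    }
    hist[ep, ] <- colMeans(acc)
  }
  list(generator = gen, discriminator = disc,
       history = as.data.frame(cbind(epoch = seq_len(config$epochs), hist)),
       config = config)
}

onehot <- function(labels, classes) {
  idx <- match(labels, classes)
  oh <- matrix(0, length(classes), length(labels))
  oh[cbind(idx, seq_along(labels))] <- 1
  oh
}

# Gradient of the label embedding: dJ/dE[k, ] = sum over batch items with
# label k of dz * z (elementwise product chain through zc = z * E[label, ]).
embedding_grad <- function(gen, lat, dz) {
  idx <- match(lat$labels, gen$classes)
  gE <- matrix(0, nrow(gen$embedding$params$E), ncol(gen$embedding$params$E))
  contrib <- dz * lat$z                     # latent_dim x n
  for (k in seq_len(nrow(gE)))
    if (any(idx == k))
      gE[k, ] <- rowSums(contrib[, idx == k, drop = FALSE])
  gE
}

collect_grads <- function(layers) lapply(layers, function(l) l$grads)

add_grads <- function(layers, saved) {
  for (i in seq_along(layers)) {
    g <- saved[[i]]
    if (!length(g)) next
    for (nm in names(g))
      layers[[i]]$grads[[nm]] <- layers[[i]]$grads[[nm]] + g[[nm]]
  }
  invisible()
}

#' Generate labeled synthetic SSF maps
#'
#' Draws latent vectors, conditions them on the requested labels and runs the
#' generator. Generated maps are tagged `synthetic = TRUE` and carry their
#' conditioning label.
#'
#' @param model trained result of [train_adgan()] (or a bare generator).
#' @param count number of maps.
#' @param labels conditioning labels (recycled to `count`).
#' @param seed RNG seed for the latent draw, or NULL.
#' @return List of [ssf_map()]s.
#' @export
generate_maps <- function(model, count,
                          labels = rep(c("left", "right"), length.out = count),
                          seed = NULL) {
  gen <- if (!is.null(model$generator)) model$generator else model
  if (!is.null(seed)) set.seed(seed)
  lat <- sample_latent(gen, count, labels)
  x <- generator_forward(gen, lat$zc, training = FALSE)
  lapply(seq_len(count), function(i)
    ssf_map(x[, , 1L, i], label = lat$labels[i], subject_id = "generated",
            trial_id = "generated", window_index = i - 1L,
            synthetic = TRUE))
}

#' Classify SSF maps with the auxiliary head
#'
#' Argmax of the discriminator's auxiliary class probabilities; exact ties
#' break toward the first class (`"left"`).
#'
#' @param model result of [train_adgan()] / [train_classifier()], or a bare
#'   discriminator.
#' @param maps list of [ssf_map()]s.
#' @return List with `labels` (character) and `probs` (n_classes x n).
#' @export
classify_maps <- function(model, maps) {
  disc <- if (!is.null(model$discriminator)) model$discriminator else model
  x <- maps_to_batch_array(maps, seq_along(maps))
  out <- discriminator_forward(disc, x, training = FALSE)
  idx <- apply(out$class_probs, 2, which.max)   # ties -> first class
  list(labels = disc$classes[idx], probs = out$class_probs)
}

#' Train the discriminator alone as a supervised classifier
#'
#' Trains the discriminator trunk and auxiliary class head with plain
#' cross-entropy (no adversarial terms). This is the cheap route for
#' robustness curves, augmentation sweeps, cross-validation, and the
#' parameter-recovery checks, where only the classification capacity of the
#' architecture matters.
#'
#' @param maps labeled [ssf_map()] list.
#' @param config a [train_config()] (`lr_discriminator`, `batch_size`,
#'   `epochs`, `width_scale`, `dropout_d` are honored).
#' @return List with `discriminator`, `history` (per-epoch mean
#'   cross-entropy) and `config`.
#' @export
train_classifier <- function(maps, config = train_config(epochs = 10L)) {
  labels <- ssf_labels(maps)
  if (anyNA(labels)) stop("all maps must be labeled")
  if (!is.null(config$seed)) set.seed(config$seed)
  disc <- build_discriminator(discriminator_spec(
    width_scale = config$width_scale, dropout = config$dropout_d))
  layers <- c(disc$trunk, list(disc$class_head))
  opt <- adam_state(config$lr_discriminator, config$beta1, config$beta2)
  n <- length(maps); B <- min(config$batch_size, n)
  classes <- disc$classes
  hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n - B + 1L, by = B)) {
      idx <- ord[start:(start + B - 1L)]
      x <- maps_to_batch_array(maps, idx)
      y <- labels[idx]
      feat <- layers_forward(disc$trunk, x, training = TRUE)
      logit <- dense_forward(disc$class_head, feat, TRUE)
      probs <- softmax_cols(logit)
      dlogit <- (probs - onehot(y, classes)) / B
      dfeat <- dense_backward(disc$class_head, dlogit)
      layers_backward(disc$trunk, dfeat)
      opt <- adam_update(layers, opt)
      losses <- c(losses, class_loss(probs, y))
    }
    hist[ep] <- mean(losses)
    if (!is.finite(hist[ep])) stop("non-finite loss at epoch ", ep)
  }
  list(discriminator = disc,
       history = data.frame(epoch = seq_len(config$epochs), loss = hist),
       config = config)
}
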