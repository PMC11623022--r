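#' Confusion counts for a two-class prediction
#'
#' Per-class true/false positive and negative counts; `positive` names the
#' class treated as positive in the binary formulas.
#'
#' @param pred,truth character vectors of predicted and true labels.
#' @param positive the positive class (default `"left"`).
#' @return List with `TP`, `FP`, `FN`, `TN`, `total`.
#' @export
confusion_counts <- function(pred, truth, positive = "left") {
  stopifnot(length(pred) == length(truth))
  list(TP = sum(pred == positive & truth == positive),
       FP = sum(pred == positive & truth != positive),
       FN = sum(pred != positive & truth == positive),
       TN = sum(pred != positive & truth != positive),
       total = length(pred))
}

#' Precision, recall, F-score and accuracy
#'
#' The standard formulas: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F `2*precision*recall/(precision+recall)`, accuracy = sum of per-class
#' true positives over total items. A zero denominator yields 0 for that
#' metric with `degenerate = TRUE`.
#'
#' @param counts result of [confusion_counts()].
#' @return List with `precision`, `recall`, `f_score`, `accuracy`,
#'   `degenerate`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(counts$total > 0)
  degen <- FALSE
  div <- function(num, den) {
    if (den == 0) { degen <<- TRUE; 0 } else num / den
  }
  precision <- div(counts$TP, counts$TP + counts$FP)
  recall <- div(counts$TP, counts$TP + counts$FN)
  f_score <- div(2 * recall * precision, recall + precision)
  accuracy <- (counts$TP + counts$TN) / counts$total
  list(precision = precision, recall = recall, f_score = f_score,
       accuracy = accuracy, degenerate = degen)
}

#' Similarity between real and generated map sets
#'
#' Three scalar summaries of how closely a set of generated maps matches a
#' set of real maps. These definitions are this package's operational
#' reconstruction (the quantities are conventionally reported but rarely
#' defined); they are symmetric in set sizes and stable under intensity
#' scale:
#' * `ED` — Euclidean distance between per-class mean images, averaged over
#'   classes and divided by the pixel count;
#' * `PCC` — Pearson correlation between flattened per-class mean images,
#'   averaged over classes;
#' * `KLD` — Kullback-Leibler divergence between 64-bin intensity histograms
#'   (real relative to generated) pooled over each set, with epsilon
#'   smoothing.
#'
#' @param real,generated non-empty lists of [ssf_map()]s of one shape.
#' @param bins histogram bin count for `KLD`.
#' @param eps smoothing constant added to histogram masses.
#' @return List with `ED`, `PCC`, `KLD`.
#' @export
similarity_metrics <- function(real, generated, bins = 64L, eps = 1e-8) {
  stopifnot(length(real) > 0, length(generated) > 0)
  gn <- nrow(real[[1]]$grid)
  if (nrow(generated[[1]]$grid) != gn) stop("map shape mismatch")
  classes <- sort(unique(stats::na.omit(c(ssf_labels(real),
                                          ssf_labels(generated)))))
  if (!length(classes)) classes <- NA_character_
  mean_img <- function(maps, cl) {
    sel <- if (is.na(cl)) maps else maps[ssf_labels(maps) == cl]
    if (!length(sel)) return(NULL)
    Reduce(`+`, lapply(sel, function(m) m$grid)) / length(sel)
  }
  eds <- c(); pccs <- c()
  for (cl in classes) {
    mr <- mean_img(real, cl); mg <- mean_img(generated, cl)
    if (is.null(mr) || is.null(mg)) next
    eds <- c(eds, sqrt(sum((mr - mg)^2)) / length(mr))
    pccs <- c(pccs, stats::cor(as.vector(mr), as.vector(mg)))
  }
  xr <- unlist(lapply(real, function(m) as.vector(m$grid)))
  xg <- unlist(lapply(generated, function(m) as.vector(m$grid)))
  rng <- range(c(xr, xg))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  p <- tabulate(findInterval(xr, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), bins) / length(xr)
  q <- tabulate(findInterval(xg, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), bins) / length(xg)
  p <- (p + eps) / sum(p + eps)
  q <- (q + eps) / sum(q + eps)
  list(ED = mean(eds), PCC = mean(pccs), KLD = sum(p * log(p / q)))
}

#' Gaussian perturbation of an intensity image
#'
#' Corrupts an image on the `[0, 255]` intensity scale as
#' `n * X + m * G` with `G` i.i.d. standard Gaussian per pixel, clipped back
#' to `[0, 255]`. Maps in `[-1, 1]` must be rescaled first (see
#' [ssf_to_intensity()]). The reference levels are `n = 0.5` with
#' `m` in 1, 3, 5, 7, 9, 11.
#'
#' @param image numeric matrix on the `[0, 255]` scale.
#' @param n multiplicative level.
#' @param m additive Gaussian level.
#' @param seed RNG seed, or NULL to use the current stream.
#' @return Perturbed matrix of the same shape, values in `[0, 255]`.
#' @export
perturb <- function(image, n = 0.5, m = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- n * image + m * stats::rnorm(length(image))
  dim(out) <- dim(image)
  pmin(pmax(out, 0), 255)
}

#' Map intensity-scale conversions
#'
#' Affine rescaling between the map scale `[-1, 1]` and the 8-bit intensity
#' scale `[0, 255]` used by the noise-robustness protocol.
#'
#' @param g numeric matrix.
#' @return Rescaled matrix.
#' @export
ssf_to_intensity <- function(g) (g + 1) * 127.5

#' @rdname ssf_to_intensity
#' @export
intensity_to_ssf <- function(g) g / 127.5 - 1

#' Classifier accuracy under increasing input noise
#'
#' Evaluates a trained classifier on the same test maps corrupted at `m = 0`
#' and each requested additive level (multiplicative level `n` throughout),
#' reseeding identically per level so curves are reproducible.
#'
#' @param model classifier (see [classify_maps()]).
#' @param maps labeled test maps.
#' @param levels additive noise levels `m` (0 is prepended if absent).
#' @param n multiplicative level.
#' @param seed base RNG seed; level `m` uses `seed + round(100 * m)`.
#' @return `data.frame` with `m` and `accuracy`. At `m = 0` and `n = 1` the
#'   accuracy equals the clean-set accuracy exactly.
#' @export
robustness_curve <- function(model, maps, levels = c(1, 3, 5, 7, 9, 11),
                             n = 0.5, seed = 1L) {
  truth <- ssf_labels(maps)
  levels <- unique(c(0, levels))
  acc <- vapply(levels, function(m) {
    pert <- lapply(seq_along(maps), function(i) {
      img <- ssf_to_intensity(maps[[i]]$grid)
      img <- perturb(img, n = if (m == 0) 1 else n, m = m,
                     seed = seed + round(100 * m) + i)
      mm <- maps[[i]]
      mm$grid <- intensity_to_ssf(img)
      mm
    })
    mean(classify_maps(model, pert)$labels == truth)
  }, numeric(1))
  data.frame(m = levels, accuracy = acc)
}

#' Traditional image augmentation baselines
#'
#' Rotation by the preset angles 45, 90, 135, 180 and 220 degrees
#' (nearest-neighbor resampling about the image center, zero fill outside
#' the frame) and zooming by factor 0.85 (nearest-neighbor, the shrunken
#' image center-padded back to the original size). Labels and shape are
#' never altered.
#'
#' @param maps list of [ssf_map()]s.
#' @param mode `"rotate"` (5 copies per map), `"scale"` (1 copy), or
#'   `"both"` (originals + rotated + scaled).
#' @param angles rotation angles in degrees.
#' @param zoom zoom factor for scaling.
#' @return List of augmented [ssf_map()]s.
#' @export
traditional_augment <- function(maps, mode = c("rotate", "scale", "both"),
                                angles = c(45, 90, 135, 180, 220),
                                zoom = 0.85) {
  mode <- match.arg(mode)
  rot <- function(m) lapply(angles, function(a) {
    mm <- m; mm$grid <- rotate_nn(m$grid, a); mm
  })
  sca <- function(m) { mm <- m; mm$grid <- zoom_nn(m$grid, zoom); list(mm) }
  out <- switch(mode,
                rotate = unlist(lapply(maps, rot), recursive = FALSE),
                scale = unlist(lapply(maps, sca), recursive = FALSE),
                both = c(maps,
                         unlist(lapply(maps, rot), recursive = FALSE),
                         unlist(lapply(maps, sca), recursive = FALSE)))
  out
}

# Nearest-neighbor rotation about the image center, zero fill.
rotate_nn <- function(g, angle_deg) {
  n <- nrow(g); m <- ncol(g)
  th <- angle_deg * pi / 180
  ci <- (n + 1) / 2; cj <- (m + 1) / 2
  out <- matrix(0, n, m)
  jj <- rep(seq_len(m), each = n) - cj
  ii <- rep(seq_len(n), times = m) - ci
  # inverse mapping: source = R(-theta) * target
  si <- round(cos(th) * ii + sin(th) * jj + ci)
  sj <- round(-sin(th) * ii + cos(th) * jj + cj)
  ok <- si >= 1 & si <= n & sj >= 1 & sj <= m
  out[cbind(rep(seq_len(n), times = m)[ok], rep(seq_len(m), each = n)[ok])] <-
    g[cbind(si[ok], sj[ok])]
  out
}

# Nearest-neighbor zoom to factor z < 1, center-padded back to input size.
zoom_nn <- function(g, z) {
  n <- nrow(g); m <- ncol(g)
  ns <- max(1L, round(n * z)); ms <- max(1L, round(m * z))
  src_i <- pmin(n, pmax(1L, round((seq_len(ns) - 0.5) / z + 0.5)))
  src_j <- pmin(m, pmax(1L, round((seq_len(ms) - 0.5) / z + 0.5)))
  small <- g[src_i, src_j, drop = FALSE]
  out <- matrix(0, n, m)
  oi <- floor((n - ns) / 2); oj <- floor((m - ms) / 2)
  out[oi + seq_len(ns), oj + seq_len(ms)] <- small
  out
}

#' McNemar's paired test of two classifiers
#'
#' Builds the 2x2 discordance table of per-item correctness of two
#' prediction vectors against the same truth. With fewer than `exact_limit`
#' discordant pairs the two-sided exact binomial p-value is used; otherwise
#' the continuity-corrected chi-square approximation. Zero discordant pairs
#' give p = 1.
#'
#' @param pred_a,pred_b predictions of classifiers A and B.
#' @param truth true labels.
#' @param exact_limit switchover on `b + c` (default 25).
#' @return List with `b` (A right, B wrong), `c` (A wrong, B right),
#'   `statistic` (chi-square, NA for the exact branch), `p_value`, `method`.
#' @export
mcnemar_test <- function(pred_a, pred_b, truth, exact_limit = 25L) {
  stopifnot(length(pred_a) == length(truth), length(pred_b) == length(truth))
  ra <- pred_a == truth; rb <- pred_b == truth
  b <- sum(ra & !rb); cc <- sum(!ra & rb)
  nd <- b + cc
  if (nd == 0)
    return(list(b = b, c = cc, statistic = NA_real_, p_value = 1,
                method = "exact binomial"))
  if (nd < exact_limit) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), nd, 0.5))
    list(b = b, c = cc, statistic = NA_real_, p_value = p,
         method = "exact binomial")
  } else {
    stat <- (abs(b - cc) - 1)^2 / nd
    list(b = b, c = cc, statistic = stat,
         p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
         method = "chi-square with continuity correction")
  }
}

#' Intra-subject k-fold cross-validation
#'
#' For each subject independently: stratified random split of that subject's
#' maps into `k` folds, `k` train/test rotations of the supplied training
#' function, metrics averaged over folds.
#'
#' @param maps labeled [ssf_map()]s with `subject_id` set.
#' @param k number of folds.
#' @param seed RNG seed controlling fold assignment and training.
#' @param train_fun function(train_maps) returning a classifier usable by
#'   [classify_maps()]; defaults to a small [train_classifier()].
#' @return `data.frame` with one row per subject: averaged precision,
#'   recall, F-score, accuracy.
#' @export
crossval_intra_subject <- function(maps, k = 5L, seed = 1L,
                                   train_fun = NULL) {
  if (is.null(train_fun))
    train_fun <- function(tr)
      train_classifier(tr, train_config(epochs = 4L, width_scale = 0.25,
                                        seed = NULL))
  labels <- ssf_labels(maps)
  subjects <- vapply(maps, function(m) as.character(m$subject_id), "")
  out <- NULL
  set.seed(seed)
  for (s in unique(subjects)) {
    idx <- which(subjects == s)
    lab <- labels[idx]
    cnt <- table(factor(lab, levels = c("left", "right")))
    if (min(cnt) < k)
      stop("subject ", s, " has fewer than k = ", k, " maps in some class")
    fold <- integer(length(idx))
    for (cl in unique(lab)) {
      sel <- which(lab == cl)
      fold[sel] <- sample(rep_len(seq_len(k), length(sel)))
    }
    mets <- matrix(0, k, 4)
    for (f in seq_len(k)) {
      tr <- maps[idx[fold != f]]; te <- maps[idx[fold == f]]
      model <- train_fun(tr)
      pred <- classify_maps(model, te)$labels
      mm <- classification_metrics(confusion_counts(pred, ssf_labels(te)))
      mets[f, ] <- c(mm$precision, mm$recall, mm$f_score, mm$accuracy)
    }
    out <- rbind(out, data.frame(subject = s, precision = mean(mets[, 1]),
                                 recall = mean(mets[, 2]),
                                 f_score = mean(mets[, 3]),
                                 accuracy = mean(mets[, 4])))
  }
  out
}
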