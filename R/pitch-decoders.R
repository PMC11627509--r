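# Population decoders for the represented pitch class: the PCA
# pitch-circle decoder and the complex-domain population-vector decoder,
# plus quantification of bias-induced decoded shifts.

#' Fit the PCA pitch-circle decoder
#'
#' Mean-centred linear decomposition of the training responses (stimuli
#' as examples, neurons as dimensions). Among the leading components,
#' the pair that best captures the pitch circle is selected (by the
#' resultant length of the embedding-angle vs true-pitch relation),
#' oriented so pitch increases counterclockwise. A coarse pitch circle
#' is then estimated from 24 rank-ordered bins of neighbouring training
#' stimuli (bins of 10 for the canonical 240-tone training set), and
#' refined by linear interpolation to a closed polyline at 0.05 st
#' resolution. The decoder is deliberately not cross-validated: it
#' serves as a reference frame for held-out test tones.
#'
#' @param train stimuli x neurons response matrix (>= 48 stimuli
#'   spanning the octave).
#' @param train_pcs true pitch classes of the training stimuli.
#' @param n_anchors number of coarse circle anchors (default 24).
#' @param n_comp how many leading components to search for the circle
#'   pair.
#' @param resolution polyline pitch resolution in semitones.
#' @return object of class `circle_embedding`: `coords` (training
#'   scores), `anchors`, `polyline` (`x`, `y`, `pc`), `projection`
#'   (centre + 2-column rotation), `component_pair`, `circle_quality`.
#' @export
fit_pca_circle <- function(train, train_pcs, n_anchors = 24L, n_comp = 5L,
                           resolution = 0.05) {
  stopifnot(nrow(train) == length(train_pcs))
  if (nrow(train) < 2 * n_anchors)
    stop("need at least ", 2 * n_anchors, " training stimuli")
  ctr <- colMeans(train)
  X <- sweep(train, 2, ctr)
  sv <- svd(X, nu = 0, nv = min(n_comp, ncol(X), nrow(X)))
  if (length(sv$d) < 2 || sv$d[2] < 1e-10 * sv$d[1])
    stop("degenerate (rank < 2) response matrix")
  k <- ncol(sv$v)
  scores <- X %*% sv$v
  phi <- 2 * pi * train_pcs / 12
  best <- NULL
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    th <- atan2(scores[, b], scores[, a])
    for (sgn in c(1, -1)) {
      q <- Mod(mean(exp(1i * (sgn * th - phi))))
      if (is.null(best) || q > best$q) best <- list(a = a, b = b, sgn = sgn, q = q)
    }
  }
  rot <- sv$v[, c(best$a, best$b)]
  if (best$sgn < 0) rot[, 2] <- -rot[, 2]   # pitch counterclockwise
  coords <- X %*% rot
  # rank-ordered anchor bins (ties broken by stimulus index)
  ord <- order(train_pcs, seq_along(train_pcs))
  grp <- rep(seq_len(n_anchors), each = ceiling(length(ord) / n_anchors),
             length.out = length(ord))
  anchors <- t(vapply(split(ord, grp), function(ix)
    c(colMeans(coords[ix, , drop = FALSE]),
      circular_mean_pc(train_pcs[ix])), numeric(3)))
  colnames(anchors) <- c("x", "y", "pc")
  # closed polyline, linearly interpolated to `resolution` in pitch
  poly <- do.call(rbind, lapply(seq_len(n_anchors), function(i) {
    j <- if (i == n_anchors) 1L else i + 1L
    dpc <- (anchors[j, "pc"] - anchors[i, "pc"]) %% 12
    m <- max(1L, ceiling(dpc / resolution))
    f <- (seq_len(m) - 1) / m
    cbind(x = anchors[i, "x"] + f * (anchors[j, "x"] - anchors[i, "x"]),
          y = anchors[i, "y"] + f * (anchors[j, "y"] - anchors[i, "y"]),
          pc = pitch_class(anchors[i, "pc"] + f * dpc))
  }))
  structure(list(coords = coords, anchors = anchors, polyline = poly,
                 projection = list(center = ctr, rotation = rot),
                 component_pair = c(best$a, best$b),
                 circle_quality = best$q, train_pcs = train_pcs),
            class = "circle_embedding")
}

#' @export
print.circle_embedding <- function(x, ...) {
  cat(sprintf("PCA pitch-circle embedding: components (%d, %d), circle quality %.3f, %d polyline points\n",
              x$component_pair[1], x$component_pair[2], x$circle_quality,
              nrow(x$polyline)))
  invisible(x)
}

#' Decode pitch class from a response vector
#'
#' Projects the response into the fitted 2-D plane (centred with the
#' training mean) and returns the pitch label of the closest polyline
#' point.
#'
#' @param embed a [fit_pca_circle()] embedding.
#' @param response neuron response vector, or stimuli x neurons matrix.
#' @return decoded pitch class(es) in `[0, 12)`.
#' @export
decode_pitch <- function(embed, response) {
  if (is.null(dim(response))) response <- matrix(response, 1)
  if (ncol(response) != length(embed$projection$center))
    stop("response dimensionality does not match the fitted projection")
  if (any(rowSums(abs(response)) == 0))
    stop("all-zero response: projection target undefined")
  y <- sweep(response, 2, embed$projection$center) %*% embed$projection$rotation
  px <- embed$polyline[, "x"]; py <- embed$polyline[, "y"]
  vapply(seq_len(nrow(y)), function(i) {
    d2 <- (px - y[i, 1])^2 + (py - y[i, 2])^2
    embed$polyline[which.min(d2), "pc"]
  }, numeric(1))
}

#' Complex-domain population-vector decoder
#'
#' Each neuron contributes a unit vector at the angle of its best pitch
#' class on the circle, weighted by its stimulus-normalised rate and
#' down-weighted by the empirical occurrence frequency of its best pitch
#' class (histogram over 12 bins with add-one smoothing), compensating
#' uneven BF sampling. The decoded pitch class is the angle of the
#' resultant.
#'
#' @param response neuron rate vector (or stimuli x neurons matrix).
#' @param best_pcs per-neuron best pitch classes.
#' @param max_rates per-neuron maximal rates over stimuli (> 0).
#' @param bf_prior optional per-neuron occurrence weights `P(PC_best)`;
#'   estimated from `best_pcs` when `NULL`.
#' @param tol resultant magnitude below which the decode is flagged
#'   undefined (`NA`).
#' @return decoded pitch class(es) in `[0, 12)`; `NA` where undefined.
#' @export
population_vector_decode <- function(response, best_pcs, max_rates,
                                     bf_prior = NULL, tol = 1e-9) {
  if (is.null(dim(response))) response <- matrix(response, 1)
  stopifnot(ncol(response) == length(best_pcs), all(max_rates > 0))
  if (is.null(bf_prior)) {
    bins <- floor(pitch_class(best_pcs)) %% 12
    h <- (tabulate(bins + 1L, 12) + 1) / (length(best_pcs) + 12)
    bf_prior <- h[bins + 1L]
  }
  wmat <- sweep(response, 2, max_rates, "/")
  wmat <- sweep(wmat, 2, bf_prior, "/")
  z <- wmat %*% exp(1i * 2 * pi * best_pcs / 12)
  out <- (Arg(z) * 12 / (2 * pi)) %% 12
  out[Mod(z) < tol * pmax(rowSums(abs(wmat)), 1)] <- NA_real_
  as.numeric(out)
}

#' Quantify bias-induced decoded shifts
#'
#' For each decoded test tone, the shift is the signed circular
#' deviation of the decoded from the true pitch class, sign-flipped so
#' that positive values point away from the bias centre (the repulsive
#' direction). Aggregates the mean shift and SEM per factor level.
#'
#' @param decoded data.frame with columns `decoded`, `true_pc`,
#'   `bias_center`, and any of `direction`, `length`, `gap`, `role`.
#' @return object of class `shift_result`: the per-tone table (with
#'   `shift_away`) and aggregate tables by bias length and by gap.
#' @export
measure_bias_shift <- function(decoded) {
  stopifnot(all(c("decoded", "true_pc", "bias_center") %in% names(decoded)))
  rel <- circular_step(decoded$bias_center, decoded$true_pc)
  decoded$shift_away <- sign(rel) * circular_step(decoded$true_pc,
                                                  decoded$decoded)
  agg <- function(f) {
    if (!f %in% names(decoded)) return(NULL)
    sp <- split(decoded$shift_away, decoded[[f]])
    data.frame(level = names(sp),
               mean_shift = vapply(sp, mean, 0, na.rm = TRUE),
               sem = vapply(sp, function(x)
                 stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))), 0),
               n = vapply(sp, length, 0L), row.names = NULL)
  }
  structure(list(per_tone = decoded, by_length = agg("length"),
                 by_gap = agg("gap"), by_direction = agg("direction")),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("Bias-induced decoded shift: mean %.3f st away from bias (n = %d test tones)\n",
              mean(x$per_tone$shift_away, na.rm = TRUE), nrow(x$per_tone)))
  if (!is.null(x$by_length)) {
    cat("  by bias length:\n")
    for (i in seq_len(nrow(x$by_length)))
      cat(sprintf("    L = %-3s %+.3f st (SEM %.3f)\n", x$by_length$level[i],
                  x$by_length$mean_shift[i], x$by_length$sem[i]))
  }
  invisible(x)
}

#' End-to-end decode of a simulated biased-pair experiment
#'
#' Trains the requested decoder on the trial-averaged responses to the
#' bias tones (the training set spans the octave) and decodes the test
#' pair of every sequence.
#'
#' @param sim a [simulate_experiment()] result for a biased-pair set.
#' @param decoder `"pca"` or `"popvec"`.
#' @param cells optional cell subset (e.g. from [select_units()]).
#' @param windows response windows used as the response measure.
#' @return data.frame of decoded test tones (columns `decoded`,
#'   `true_pc`, `bias_center`, `direction`, `length`, `gap`, `role`)
#'   ready for [measure_bias_shift()]; the embedding (or popvec
#'   parameters) attached as attribute `decoder`.
#' @export
decode_experiment <- function(sim, decoder = c("pca", "popvec"),
                              cells = NULL,
                              windows = c("onset", "sustained")) {
  decoder <- match.arg(decoder)
  resp <- event_responses(sim, windows)
  if (!is.null(cells)) resp <- resp[, cells, drop = FALSE]
  ev <- sim$events
  train <- ev$role %in% c("bias", "lead_in")
  test <- ev$role %in% c("test1", "test2", "probe")
  bias_meta <- do.call(rbind, lapply(sim$sequences, function(s)
    data.frame(center = s$bias_meta$center, direction = s$bias_meta$direction,
               length = s$bias_meta$length, gap = s$bias_meta$gap)))
  if (decoder == "pca") {
    embed <- fit_pca_circle(resp[train, , drop = FALSE],
                            ev$pitch_class[train])
    dec <- decode_pitch(embed, resp[test, , drop = FALSE])
  } else {
    tr <- resp[train, , drop = FALSE]
    best <- ev$pitch_class[train][apply(tr, 2, which.max)]
    mx <- apply(tr, 2, max)
    mx[mx <= 0] <- 1e-9
    embed <- list(best_pcs = best, max_rates = mx)
    dec <- population_vector_decode(resp[test, , drop = FALSE], best, mx)
  }
  out <- data.frame(decoded = dec, true_pc = ev$pitch_class[test],
                    bias_center = bias_meta$center[ev$seq[test]],
                    direction = bias_meta$direction[ev$seq[test]],
                    length = bias_meta$length[ev$seq[test]],
                    gap = bias_meta$gap[ev$seq[test]],
                    role = ev$role[test])
  attr(out, "decoder") <- embed
  out
}
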