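# Electrical impedance spectra and CLAFIC subspace classification.
#
# CLAFIC (class-featuring information compression) builds, per class, the
# principal subspace of the uncentred second-moment matrix of unit-norm
# feature vectors; an unknown spectrum is assigned to the class whose
# subspace captures the largest squared projection length. With uncentred,
# unit-norm features the k = 1 basis vector is approximately the class mean
# direction, and projection lengths of unit vectors lie in [0, 1].

#' Impedance spectrum with derived quantities
#'
#' Stores a frequency-indexed complex impedance spectrum and derives the
#' magnitude `|Z| = sqrt(Z_Re^2 + Z_Im^2)` and the loss factor (phase angle)
#' `delta = atan(Z_Im / Z_Re)`; negative loss factors are capacitive,
#' positive inductive.
#'
#' @param frequency_hz Frequencies, Hz.
#' @param z_re,z_im Real and imaginary parts of the impedance, Ohm.
#' @param sample_id,tissue,class Optional labels (tissue: `"root"` or
#'   `"stem"`).
#' @return Data frame of class `"eis_spectrum"` with added columns
#'   `magnitude` and `delta` (rad).
#' @export
eis_spectrum <- function(frequency_hz, z_re, z_im,
                         sample_id = NA_character_, tissue = NA_character_,
                         class = NA_character_) {
  stopifnot(length(frequency_hz) == length(z_re),
            length(z_re) == length(z_im), all(frequency_hz > 0))
  out <- data.frame(
    sample_id = sample_id, tissue = tissue, class = class,
    frequency_hz = frequency_hz, z_re = z_re, z_im = z_im,
    magnitude = sqrt(z_re^2 + z_im^2),
    delta = atan2(z_im, z_re)
  )
  class(out) <- c("eis_spectrum", "data.frame")
  out
}

#' Feature vector from an impedance spectrum
#'
#' Restricts one derived quantity of the spectrum to a frequency window
#' (default 150 Hz to 150 kHz, the classification window) and scales the
#' resulting vector to unit norm, making classification invariant to
#' per-spectrum positive scaling.
#'
#' @param spectrum An [eis_spectrum()] (or data frame with `frequency_hz`
#'   and the requested quantity column).
#' @param quantity One of `"z_re"`, `"z_im"`, `"delta"`, `"magnitude"`.
#' @param window `c(low, high)` frequency window, Hz.
#' @param normalize Scale to unit norm (default); disable to keep raw values.
#' @return Numeric feature vector (frequencies in ascending order).
#' @export
spectrum_features <- function(spectrum,
                              quantity = c("z_re", "z_im", "delta", "magnitude"),
                              window = c(150, 150e3), normalize = TRUE) {
  quantity <- match.arg(quantity)
  keep <- spectrum$frequency_hz >= window[1] & spectrum$frequency_hz <= window[2]
  if (!any(keep)) stop("empty frequency window", call. = FALSE)
  x <- spectrum[[quantity]][keep][order(spectrum$frequency_hz[keep])]
  if (normalize) {
    nrm <- sqrt(sum(x^2))
    if (nrm == 0) stop("zero feature vector cannot be normalized", call. = FALSE)
    x <- x / nrm
  }
  x
}

#' Fit a CLAFIC subspace model
#'
#' For each class, computes the top-`k` eigenvectors of the uncentred
#' second-moment matrix of that class's feature vectors. Feature vectors are
#' unit-normalized rows.
#'
#' @param features Numeric matrix, one feature vector per row.
#' @param labels Class labels, one per row.
#' @param k Subspace dimension; must not exceed any class size or the
#'   feature dimension.
#' @return Object of class `"clafic_model"`: list of per-class orthonormal
#'   bases (columns), plus `k` and `classes`.
#' @export
clafic_fit <- function(features, labels, k = 2L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels), k >= 1L)
  if (k > ncol(features)) stop("k exceeds the feature dimension", call. = FALSE)
  nrm <- sqrt(rowSums(features^2))
  features <- features / nrm
  classes <- sort(unique(labels))
  bases <- lapply(classes, function(cl) {
    X <- features[labels == cl, , drop = FALSE]
    if (nrow(X) < k) {
      stop(sprintf("class %s has %d samples, fewer than k = %d",
                   cl, nrow(X), k), call. = FALSE)
    }
    M <- crossprod(X) / nrow(X)
    eigen(M, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  })
  names(bases) <- classes
  structure(list(bases = bases, k = k, classes = classes),
            class = "clafic_model")
}

#' Classify a feature vector with a CLAFIC model
#'
#' Projects the (unit-normalized) vector onto each class subspace and assigns
#' the class with the largest squared projection length. Exact ties are
#' flagged ambiguous and all tied classes are reported.
#'
#' @param model A [clafic_fit()] model.
#' @param x Numeric feature vector.
#' @return List: `class` (winner, or all tied classes), `projection`
#'   (named squared projection lengths), `ambiguous` (logical).
#' @export
clafic_classify <- function(model, x) {
  stopifnot(inherits(model, "clafic_model"))
  x <- x / sqrt(sum(x^2))
  proj <- vapply(model$bases, function(B) sum(crossprod(B, x)^2), numeric(1))
  top <- max(proj)
  winners <- names(proj)[proj >= top - 1e-12]
  list(class = winners, projection = proj, ambiguous = length(winners) > 1L)
}

#' Evaluate CLAFIC classification success over subspace dimensions
#'
#' For each subspace dimension `k`, classifies every sample under
#' resubstitution (model fitted on all data) and leave-one-out (per-sample
#' refit without that sample) and reports the fraction of correct,
#' unambiguous assignments together with the confusion matrix. Dimensions
#' equal to the full feature dimension are degenerate (every projection
#' length is 1) and are reported with `degenerate = TRUE`.
#'
#' @param features Numeric matrix, one feature vector per row.
#' @param labels Class labels.
#' @param k_range Integer vector of subspace dimensions.
#' @return List of class `"clafic_evaluation"`: `success` data frame
#'   (`k`, `resubstitution`, `leave_one_out`, `degenerate`) and `confusion`,
#'   a per-k list of leave-one-out confusion matrices (true x assigned).
#' @export
clafic_evaluate <- function(features, labels, k_range = 1:6) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  classes <- sort(unique(labels))
  success <- data.frame(k = integer(0), resubstitution = numeric(0),
                        leave_one_out = numeric(0), degenerate = logical(0))
  confusion <- list()
  for (k in k_range) {
    model <- clafic_fit(features, labels, k)
    resub <- vapply(seq_len(n), function(i) {
      r <- clafic_classify(model, features[i, ])
      !r$ambiguous && identical(r$class, labels[i])
    }, logical(1))
    loo_assign <- character(n)
    loo_ok <- logical(n)
    for (i in seq_len(n)) {
      mi <- clafic_fit(features[-i, , drop = FALSE], labels[-i], k)
      r <- clafic_classify(mi, features[i, ])
      loo_assign[i] <- if (r$ambiguous) NA_character_ else r$class
      loo_ok[i] <- !r$ambiguous && identical(r$class, labels[i])
    }
    success <- rbind(success, data.frame(
      k = k, resubstitution = mean(resub), leave_one_out = mean(loo_ok),
      degenerate = k >= ncol(features)
    ))
    confusion[[as.character(k)]] <-
      table(true = factor(labels, classes),
            assigned = factor(loo_assign, classes))
  }
  structure(list(success = success, confusion = confusion, classes = classes),
            class = "clafic_evaluation")
}

#' @export
print.clafic_evaluation <- function(x, ...) {
  cat("CLAFIC classification success by subspace dimension\n")
  print(x$success, row.names = FALSE)
  invisible(x)
}
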