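#' Interval-censored observation set
#'
#' Container for interval-censored event times. Each observation states that
#' the event (root death) occurred in the half-open interval `(left, right]`.
#' `right = Inf` denotes right-censoring (the root was still alive at the last
#' imaging session). `left == right` denotes an exactly observed event time.
#'
#' @param left Numeric vector of exclusive left bounds (days).
#' @param right Numeric vector of inclusive right bounds; `Inf` for
#'   right-censored observations.
#' @param group Optional group labels (e.g. soil-temperature treatment).
#' @param id Optional observation identifiers.
#'
#' @return A data frame of class `"ic_set"` with columns `left`, `right` and,
#'   when supplied, `group` and `id`.
#' @export
#' @examples
#' ic_intervals(c(0, 1, 2), c(2, 3, 4))
ic_intervals <- function(left, right, group = NULL, id = NULL) {
  left <- as.numeric(left)
  right <- as.numeric(right)
  if (length(left) != length(right)) {
    stop("`left` and `right` must have the same length", call. = FALSE)
  }
  if (length(left) == 0L) stop("need at least one interval", call. = FALSE)
  if (anyNA(left) || anyNA(right)) stop("interval bounds must not be NA", call. = FALSE)
  if (any(left > right)) {
    bad <- which(left > right)
    stop("left bound exceeds right bound for observation(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(is.infinite(left))) stop("left bounds must be finite", call. = FALSE)
  out <- data.frame(left = left, right = right)
  if (!is.null(id)) out$id <- id
  if (!is.null(group)) out$group <- as.character(group)
  class(out) <- c("ic_set", "data.frame")
  out
}

as_ic_set <- function(x) {
  if (inherits(x, "ic_set")) return(x)
  if (is.data.frame(x) && all(c("left", "right") %in% names(x))) {
    return(ic_intervals(x$left, x$right,
                        group = if ("group" %in% names(x)) x$group,
                        id = if ("id" %in% names(x)) x$id))
  }
  stop("cannot interpret input as an interval-censored set", call. = FALSE)
}

# Maximal intersections (innermost / Turnbull intervals) of a set of
# (left, right] intervals. Exact observations (left == right) are first
# shifted to (t - eps, t] so a single open-left/closed-right convention
# covers everything; eps is far below the data resolution, so reported
# boundaries are unaffected at any realistic tolerance.
#
# Construction: sort the multiset of endpoints, right endpoints before left
# endpoints at ties; every left endpoint immediately followed by a right
# endpoint delimits an innermost interval.
turnbull_intervals <- function(left, right) {
  vals <- c(left, right)
  type <- rep(c(1L, 0L), each = length(left)) # left = 1 sorts after right = 0
  ord <- order(vals, type)
  v <- vals[ord]
  ty <- type[ord]
  q <- numeric(0)
  p <- numeric(0)
  for (i in seq_len(length(v) - 1L)) {
    if (ty[i] == 1L && ty[i + 1L] == 0L) {
      q <- c(q, v[i])
      p <- c(p, v[i + 1L])
    }
  }
  keep <- !duplicated(paste(q, p))
  data.frame(q = q[keep], p = p[keep])
}

#' Turnbull nonparametric maximum-likelihood survival estimate
#'
#' Computes the NPMLE of the survival function from interval-censored event
#' times by self-consistency (EM) iteration. Probability mass is placed only
#' on the maximal intersections (innermost intervals) of the observation
#' intervals; within an innermost interval of positive width the NPMLE is
#' non-unique, and such regions are flagged so downstream summaries can apply
#' the conventional descending-slope (linear) interpolation.
#'
#' On exact event times the estimator reduces to the complement of the
#' empirical distribution function; on right-censored-only data it reduces to
#' the Kaplan-Meier product-limit estimate.
#'
#' @param data An [ic_intervals()] set, or a data frame with columns `left`
#'   and `right`.
#' @param tol Convergence tolerance on the maximum absolute change in interval
#'   masses between EM iterations.
#' @param max_iter Iteration cap; non-convergence raises an error. The
#'   default is generous because each iteration is a single matrix product
#'   and the self-consistency iteration converges slowly when the likelihood
#'   is nearly flat across adjacent innermost intervals.
#'
#' @return An object of class `"turnbull_npmle"`: a list with `intervals`
#'   (data frame of innermost intervals `left`, `right`, `mass`, logical
#'   `nonunique`), `n`, `iterations`, `converged`, and `loglik` (final
#'   log-likelihood).
#' @seealso [survival_at()], [median_longevity()], [mean_longevity()]
#' @export
#' @examples
#' fit <- turnbull_npmle(ic_intervals(c(0, 1, 2), c(2, 3, 4)))
#' fit$intervals
turnbull_npmle <- function(data, tol = 1e-8, max_iter = 100000L) {
  stopifnot(tol > 0, max_iter >= 1)
  data <- as_ic_set(data)
  left <- data$left
  right <- data$right
  n <- length(left)

  # exact observations -> (t - eps, t]
  exact <- left == right
  eps <- 0
  if (any(exact)) {
    fin <- unique(c(left, right[is.finite(right)]))
    scale <- max(abs(fin), 1)
    eps <- scale * 1e-9
    left[exact] <- left[exact] - eps
  }

  ti <- turnbull_intervals(left, right)
  m <- nrow(ti)
  if (m == 0L) stop("no innermost intervals found; degenerate input", call. = FALSE)

  # containment: innermost (q, p] inside observation (L, R]
  A <- outer(left, ti$q, `<=`) & outer(right, ti$p, `>=`)
  storage.mode(A) <- "double"
  if (any(rowSums(A) == 0)) {
    stop("internal error: observation not covered by any innermost interval",
         call. = FALSE)
  }

  s <- rep(1 / m, m)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    denom <- as.vector(A %*% s)
    ll <- sum(log(denom))
    if (ll < ll_old - 1e-10) {
      stop("log-likelihood decreased during EM; numerical failure", call. = FALSE)
    }
    ll_old <- ll
    s_new <- s * as.vector(crossprod(A, 1 / denom)) / n
    delta <- max(abs(s_new - s))
    s <- s_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(
      "Turnbull EM did not converge in %d iterations (last max mass change %.3e)",
      max_iter, delta), call. = FALSE)
  }
  s <- s / sum(s)

  degenerate <- (ti$p - ti$q) <= 2 * eps & is.finite(ti$p)
  intervals <- data.frame(
    left = ifelse(degenerate, ti$p, ti$q),
    right = ti$p,
    mass = s,
    nonunique = s > tol & !degenerate
  )
  structure(
    list(intervals = intervals, n = n, iterations = iter,
         converged = converged, loglik = ll_old),
    class = "turnbull_npmle"
  )
}

#' @export
print.turnbull_npmle <- function(x, ...) {
  cat("Turnbull NPMLE of the survival function\n")
  cat(sprintf("  n = %d observations, %d innermost intervals, %d EM iterations\n",
              x$n, nrow(x$intervals), x$iterations))
  cens <- sum(!is.finite(x$intervals$right) & x$intervals$mass > 1e-8)
  if (cens > 0) cat("  right-censored tail mass present\n")
  print(x$intervals, ...)
  invisible(x)
}

# survival levels just before and just after each innermost interval
curve_levels <- function(curve) {
  mass <- curve$intervals$mass
  s_left <- 1 - cumsum(c(0, mass[-length(mass)]))
  s_right <- s_left - mass
  list(s_left = s_left, s_right = pmax(s_right, 0))
}

#' Evaluate a Turnbull survival curve
#'
#' Evaluates `S(t) = P(T > t)`. Between innermost intervals the NPMLE is a
#' uniquely defined step function; inside an innermost interval of positive
#' width it is non-unique and the conventional descending slope (linear
#' interpolation between the interval's endpoints) is used as an ad-hoc
#' estimate. Beyond a right-censored tail interval the curve is extended as a
#' constant at its last defined level.
#'
#' @param curve A [turnbull_npmle()] fit.
#' @param t Numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "turnbull_npmle"))
  iv <- curve$intervals
  lv <- curve_levels(curve)
  vapply(t, function(tt) {
    if (tt < iv$left[1] || nrow(iv) == 0L) return(1)
    s <- 1
    for (j in seq_len(nrow(iv))) {
      if (is.finite(iv$right[j]) && tt >= iv$right[j]) {
        s <- lv$s_right[j]
        next
      }
      if (tt <= iv$left[j]) return(s)
      # inside (left_j, right_j)
      if (!is.finite(iv$right[j])) return(lv$s_left[j]) # censored tail
      w <- (tt - iv$left[j]) / (iv$right[j] - iv$left[j])
      return(lv$s_left[j] - w * iv$mass[j])
    }
    s
  }, numeric(1))
}

#' Median longevity from a Turnbull survival curve
#'
#' The median is the first time at which the NPMLE survival curve goes below
#' 0.5 (strict inequality). Within a non-unique region the crossing time of
#' the descending slope is used. Returns `NA` (with a warning) if the curve
#' never goes below 0.5, as under heavy right-censoring.
#'
#' @param curve A [turnbull_npmle()] fit.
#' @return Median event time in the input time unit (days), or `NA`.
#' @export
median_longevity <- function(curve) {
  stopifnot(inherits(curve, "turnbull_npmle"))
  iv <- curve$intervals
  lv <- curve_levels(curve)
  for (j in seq_len(nrow(iv))) {
    if (lv$s_right[j] < 0.5 - 1e-12) {
      if (!is.finite(iv$right[j])) {
        warning("survival curve only crosses 0.5 inside the censored tail; median undefined",
                call. = FALSE)
        return(NA_real_)
      }
      width <- iv$right[j] - iv$left[j]
      if (width <= 0 || !iv$nonunique[j]) return(iv$right[j])
      tt <- iv$left[j] + (lv$s_left[j] - 0.5) / iv$mass[j] * width
      return(min(max(tt, iv$left[j]), iv$right[j]))
    }
  }
  warning("survival curve never goes below 0.5; median undefined", call. = FALSE)
  NA_real_
}

#' Restricted mean longevity from a Turnbull survival curve
#'
#' Integrates the survival curve from time zero to `horizon`, applying the
#' descending-slope convention across non-unique regions. With a
#' right-censored tail the integral is restricted to the largest finite
#' interval boundary (restricted mean), which is also the default horizon.
#'
#' @param curve A [turnbull_npmle()] fit.
#' @param horizon Upper integration limit (days); defaults to the largest
#'   finite innermost-interval boundary.
#' @return Restricted mean event time (days).
#' @export
mean_longevity <- function(curve, horizon = NULL) {
  stopifnot(inherits(curve, "turnbull_npmle"))
  iv <- curve$intervals
  lv <- curve_levels(curve)
  fin <- c(iv$left[is.finite(iv$left)], iv$right[is.finite(iv$right)])
  if (is.null(horizon)) horizon <- max(fin)
  pos <- 0
  s <- 1
  total <- 0
  for (j in seq_len(nrow(iv))) {
    a <- min(iv$left[j], horizon)
    if (a > pos) {
      total <- total + s * (a - pos) # flat gap before the interval
      pos <- a
    }
    if (pos >= horizon) break
    if (!is.finite(iv$right[j])) break # censored tail: restrict here
    b <- min(iv$right[j], horizon)
    if (b > iv$left[j]) { # descending slope across the non-unique region
      s_b <- lv$s_left[j] -
        iv$mass[j] * (b - iv$left[j]) / (iv$right[j] - iv$left[j])
      total <- total + (s + s_b) / 2 * (b - pos)
      s <- s_b
      pos <- b
    } else {
      s <- lv$s_right[j] # step (exact observation)
    }
    if (pos >= horizon) break
  }
  if (pos < horizon) total <- total + s * (horizon - pos)
  total
}
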