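# Simplex (Aitchison) geometry for D-part time-use compositions.
#
# A composition carries only relative information: a day described by
# (sleep, SED, LPA, MVPA) minutes is equivalent to any positive rescaling
# of itself. All operations below act on the closed simplex and none of
# the kernels hard-wires D = 4; the movement-behaviour part order
# (sleep, SED, LPA, MVPA) is fixed by `behavior_parts()` and the default
# sequential binary partition.

#' Canonical movement-behaviour part names
#'
#' @return Character vector `c("sleep", "sed", "lpa", "mvpa")`, the fixed
#'   part order used throughout the package.
#' @export
behavior_parts <- function() c("sleep", "sed", "lpa", "mvpa")

#' Close a composition to a constant sum
#'
#' Rescales each observation so its parts sum to `kappa` (1 for
#' proportions, 1440 for minutes of a 24-h day).
#'
#' @param x Numeric vector of parts, or a matrix/data.frame with one
#'   observation per row.
#' @param kappa Closure constant (default 1).
#' @return Object of the same shape as `x`, each observation summing to
#'   `kappa`.
#' @examples
#' close_composition(c(sleep = 478, sed = 672, lpa = 239, mvpa = 50), 1440)
#' @export
close_composition <- function(x, kappa = 1) {
  m <- as_comp_matrix(x)
  if (any(!is.finite(m)) || any(m < 0))
    stop("composition parts must be finite and nonnegative")
  s <- rowSums(m)
  if (any(s <= 0)) stop("cannot close an all-zero composition")
  restore_shape(m * (kappa / s), m)
}

#' Multiplicative replacement of zeros below a detection limit
#'
#' Rounded zeros (here: days with no recorded MVPA) are replaced by
#' `frac * detection_limit` and the remaining parts are multiplicatively
#' scaled down so each observation's total is preserved. With minutes and
#' the default settings a zero becomes 0.65 min and nonzero parts are
#' scaled by `(1440 - 0.65) / 1440` for a 1440-min day.
#'
#' @param x Composition vector or matrix in the same units as
#'   `detection_limit` (minutes by default).
#' @param detection_limit Smallest observable value (default 1 minute).
#' @param frac Fraction of the detection limit used for the imputed value
#'   (default 0.65).
#' @return `x` with zeros replaced; strictly positive, totals preserved.
#' @export
replace_zeros <- function(x, detection_limit = 1, frac = 0.65) {
  m <- as_comp_matrix(x)
  if (any(m < 0)) stop("composition parts must be nonnegative")
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("a composition that is entirely zero cannot be imputed")
  delta <- frac * detection_limit
  out <- m
  for (i in seq_len(nrow(m))) {
    z <- m[i, ] == 0
    if (!any(z)) next
    imputed <- sum(z) * delta
    if (imputed >= tot[i]) stop("imputed mass exceeds the composition total")
    out[i, z] <- delta
    out[i, !z] <- m[i, !z] * (1 - imputed / tot[i])
  }
  restore_shape(out, m)
}

#' Perturbation: the simplex group operation
#'
#' Component-wise product followed by closure; the compositional analogue
#' of addition. `perturb_diff(post, pre)` is the analogue of subtraction
#' and returns the change composition `close(post / pre)`, the standard
#' pre-to-post change summary of compositional time-use studies.
#'
#' @param x,p,post,pre Strictly positive compositions (vector or matrix).
#' @param kappa Closure constant of the result.
#' @return A composition closed to `kappa`.
#' @export
perturb <- function(x, p, kappa = 1) {
  xm <- as_comp_matrix(x)
  pm <- as_comp_matrix(p)
  if (ncol(xm) != ncol(pm)) stop("part counts differ")
  if (nrow(pm) == 1L && nrow(xm) > 1L) pm <- pm[rep(1L, nrow(xm)), , drop = FALSE]
  close_composition(restore_shape(xm * pm, xm), kappa)
}

#' @rdname perturb
#' @export
perturb_diff <- function(post, pre, kappa = 1) {
  postm <- as_comp_matrix(post)
  prem <- as_comp_matrix(pre)
  if (ncol(postm) != ncol(prem)) stop("part counts differ")
  if (nrow(prem) == 1L && nrow(postm) > 1L) prem <- prem[rep(1L, nrow(postm)), , drop = FALSE]
  if (any(prem <= 0)) stop("reference composition must be strictly positive")
  close_composition(restore_shape(postm / prem, postm), kappa)
}

#' @rdname perturb
#' @export
perturb_inverse <- function(x, kappa = 1) {
  m <- as_comp_matrix(x)
  if (any(m <= 0)) stop("composition must be strictly positive")
  close_composition(restore_shape(1 / m, m), kappa)
}

#' Compositional (geometric) mean
#'
#' Closure of the component-wise geometric means — the centre of a
#' compositional sample, rescaled to `kappa` (1440 min by default so the
#' centre reads as minutes of a 24-h day).
#'
#' @param x Matrix/data.frame of strictly positive compositions, one row
#'   per observation.
#' @param kappa Closure constant of the result (default 1440).
#' @return Named numeric vector, the closed geometric mean.
#' @export
compositional_mean <- function(x, kappa = 1440) {
  m <- as_comp_matrix(x)
  if (nrow(m) == 0L) stop("cannot average an empty set of compositions")
  if (any(m <= 0)) stop("compositional mean requires strictly positive parts; see replace_zeros()")
  g <- exp(colMeans(log(m)))
  close_composition(g, kappa)
}

# ---- sequential binary partition and balances --------------------------

#' Sequential binary partition (SBP)
#'
#' An SBP encodes D-1 nested binary splits of the D parts as sign rows
#' (+1 = numerator group, -1 = denominator group, 0 = not involved); each
#' row defines one balance coordinate. Rows must be nested: the parts a
#' row splits must carry a single sign in every earlier row.
#'
#' @param rows Numeric matrix with D-1 rows and D columns, entries in
#'   {-1, 0, 1}. Column names name the parts, row names the balances.
#' @return Validated matrix of class `"sbp"`.
#' @seealso [default_sbp()] for the movement-behaviour partition.
#' @export
sbp <- function(rows) {
  m <- as.matrix(rows)
  storage.mode(m) <- "double"
  if (!all(m %in% c(-1, 0, 1))) stop("SBP entries must be -1, 0 or +1")
  if (nrow(m) != ncol(m) - 1L)
    stop("an SBP for D parts must have D - 1 rows")
  for (k in seq_len(nrow(m))) {
    if (!any(m[k, ] > 0) || !any(m[k, ] < 0))
      stop(sprintf("SBP row %d needs at least one positive and one negative part", k))
    if (k > 1L) {
      active <- m[k, ] != 0
      for (j in seq_len(k - 1L)) {
        if (length(unique(m[j, active])) > 1L)
          stop(sprintf("SBP is not nested: row %d splits parts that row %d separates", k, j))
      }
    }
  }
  structure(m, class = c("sbp", "matrix"))
}

#' Default movement-behaviour partition
#'
#' Balance 1 contrasts the active behaviours (LPA, MVPA; positive) with
#' the passive ones (sleep, SED); balance 2 contrasts LPA (positive) with
#' MVPA; balance 3 contrasts SED (positive) with sleep.
#'
#' @return An [sbp()] for the parts `behavior_parts()`.
#' @export
default_sbp <- function() {
  m <- rbind(
    active_vs_passive = c(-1, -1, 1, 1),
    lpa_vs_mvpa       = c(0, 0, 1, -1),
    sed_vs_sleep      = c(-1, 1, 0, 0)
  )
  colnames(m) <- behavior_parts()
  sbp(m)
}

#' Balance-coordinate (ilr) transform
#'
#' Maps a strictly positive D-part composition to D-1 real balance
#' coordinates. Row k of the SBP with r positive and s negative parts
#' yields
#' \deqn{z_k = \sqrt{rs/(r+s)} \, \ln\frac{g(\mathrm{pos})}{g(\mathrm{neg})}}
#' where g() is the geometric mean of the group. Coordinates are invariant
#' to rescaling of the composition.
#'
#' @param x Strictly positive composition vector or matrix.
#' @param partition An [sbp()]; defaults to [default_sbp()].
#' @return Numeric vector (or matrix, one row per observation) of balance
#'   coordinates, named after the SBP rows.
#' @export
ilr_transform <- function(x, partition = default_sbp()) {
  m <- as_comp_matrix(x)
  if (ncol(m) != ncol(partition))
    stop("composition and partition disagree on the number of parts")
  if (any(m <= 0))
    stop("balance coordinates need strictly positive parts; apply replace_zeros() first")
  lx <- log(m)
  z <- matrix(0, nrow(m), nrow(partition),
              dimnames = list(rownames(m), rownames(partition)))
  for (k in seq_len(nrow(partition))) {
    pos <- partition[k, ] > 0
    neg <- partition[k, ] < 0
    r <- sum(pos); s <- sum(neg)
    log_gm_pos <- rowMeans(lx[, pos, drop = FALSE])
    log_gm_neg <- rowMeans(lx[, neg, drop = FALSE])
    z[, k] <- sqrt(r * s / (r + s)) * (log_gm_pos - log_gm_neg)
  }
  restore_shape(z, m)
}

# Orthonormal contrast matrix of an SBP ((D-1) x D); rows are the ilr
# basis vectors. Used by the inverse transform.
sbp_contrast_matrix <- function(partition) {
  D <- ncol(partition)
  V <- matrix(0, nrow(partition), D, dimnames = dimnames(partition))
  for (k in seq_len(nrow(partition))) {
    pos <- partition[k, ] > 0
    neg <- partition[k, ] < 0
    r <- sum(pos); s <- sum(neg)
    V[k, pos] <- sqrt(s / (r * (r + s)))
    V[k, neg] <- -sqrt(r / (s * (r + s)))
  }
  V
}

#' Inverse balance-coordinate transform
#'
#' Recovers the unique composition (up to closure) whose balance
#' coordinates equal `z`.
#'
#' @param z Numeric vector of D-1 coordinates, or matrix with one row per
#'   observation.
#' @param partition An [sbp()].
#' @param kappa Closure constant of the result.
#' @return Strictly positive composition(s) closed to `kappa`.
#' @export
ilr_inverse <- function(z, partition = default_sbp(), kappa = 1) {
  zm <- if (is.null(dim(z))) matrix(z, nrow = 1L) else as.matrix(z)
  if (ncol(zm) != nrow(partition))
    stop("coordinate count does not match the partition")
  if (any(!is.finite(zm))) stop("coordinates must be finite")
  V <- sbp_contrast_matrix(partition)
  x <- exp(zm %*% V)
  colnames(x) <- colnames(partition)
  out <- close_composition(x, kappa)
  if (is.null(dim(z))) drop(out) else out
}

# ---- sub-compositions and ternary geometry -----------------------------

#' Leave-one-out three-part sub-compositions
#'
#' @param x A 4-part composition vector or matrix.
#' @return Named list of four closed 3-part compositions (names give the
#'   retained parts).
#' @export
subcompositions <- function(x) {
  m <- as_comp_matrix(x)
  D <- ncol(m)
  nm <- colnames(m) %||% paste0("part", seq_len(D))
  out <- lapply(seq_len(D), function(drop_i) {
    sub <- m[, -drop_i, drop = FALSE]
    close_composition(restore_shape(sub, m), 1)
  })
  names(out) <- vapply(seq_len(D), function(i) paste(nm[-i], collapse = "_"), "")
  out
}

#' Barycentric ternary coordinates
#'
#' Maps 3-part compositions onto the unit triangle with corners
#' (0, 0), (1, 0) and (1/2, sqrt(3)/2) for the first, second and third
#' part respectively. Invariant to rescaling of the input.
#'
#' @param x 3-part composition vector or matrix.
#' @return Matrix (or length-2 vector) of plane coordinates `x`, `y`.
#' @export
ternary_coords <- function(x) {
  m <- as_comp_matrix(x)
  if (ncol(m) != 3L) stop("ternary coordinates need exactly 3 parts")
  p <- close_composition(m, 1)
  p <- as_comp_matrix(p)
  xy <- cbind(x = p[, 2L] + 0.5 * p[, 3L], y = sqrt(3) / 2 * p[, 3L])
  restore_shape(xy, m)
}

# 2-D balance basis for a triple: part1 vs rest, then part2 vs part3.
triple_sbp <- function(part_names = c("a", "b", "c")) {
  m <- rbind(c(1, -1, -1), c(0, 1, -1))
  colnames(m) <- part_names
  rownames(m) <- c("first_vs_rest", "second_vs_third")
  sbp(m)
}

#' Bootstrapped confidence region for a compositional mean
#'
#' Bootstrap resamples of the compositional mean of 3-part samples are
#' mapped to a 2-D balance-coordinate plane; assuming normality there, the
#' region is the ellipse of squared Mahalanobis distance up to the
#' `level` quantile of a chi-square with 2 df around the bootstrap centre,
#' back-mapped to the simplex.
#'
#' @param samples Matrix/data.frame of strictly positive 3-part
#'   compositions, at least 3 distinct rows.
#' @param level Coverage probability (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param seed Integer seed; the region is deterministic given the seed.
#' @param n_points Number of boundary points traced (default 128).
#' @return Object of class `"ternary_region"`: list with `center` (3-part,
#'   closed to 1), `boundary` (`n_points` x 3 matrix tracing the contour,
#'   first point repeated last), `level`, and the logratio-plane `center_z`,
#'   `cov_z`, `radius2` used by [region_contains()]. Degenerate samples
#'   give a point region (`degenerate = TRUE`).
#' @export
confidence_region <- function(samples, level = 0.95, n_boot = 500, seed = 1,
                              n_points = 128) {
  m <- as_comp_matrix(samples)
  if (ncol(m) != 3L) stop("confidence regions are computed for 3-part compositions")
  if (nrow(unique(round(close_composition(m, 1), 12))) < 3L && nrow(m) >= 3L) {
    # fewer than 3 distinct points: fall through to degenerate handling
  }
  if (nrow(m) < 3L) stop("need at least 3 samples")
  part_names <- colnames(m) %||% c("a", "b", "c")
  part <- triple_sbp(part_names)
  z <- ilr_transform(close_composition(m, 1), part)
  boot_means <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(z), replace = TRUE)
      colMeans(z[idx, , drop = FALSE])
    }, numeric(2L)))
  })
  center_z <- colMeans(boot_means)
  S <- stats::cov(boot_means)
  radius2 <- stats::qchisq(level, df = 2)
  ev <- eigen(S, symmetric = TRUE)
  degenerate <- any(ev$values < 1e-14)
  center <- ilr_inverse(center_z, part, kappa = 1)
  if (degenerate) {
    boundary <- matrix(rep(center, each = n_points + 1L), ncol = 3L,
                       dimnames = list(NULL, part_names))
  } else {
    theta <- seq(0, 2 * pi, length.out = n_points + 1L)
    circle <- cbind(cos(theta), sin(theta))
    # map unit circle through sqrt of covariance, scaled to the chi-square radius
    A <- ev$vectors %*% diag(sqrt(ev$values * radius2))
    bz <- sweep(circle %*% t(A), 2L, center_z, "+")
    boundary <- ilr_inverse(bz, part, kappa = 1)
  }
  structure(list(center = center, boundary = boundary, level = level,
                 center_z = center_z, cov_z = S, radius2 = radius2,
                 degenerate = degenerate, partition = part),
            class = "ternary_region")
}

#' @export
print.ternary_region <- function(x, ...) {
  cat(sprintf("ternary confidence region (level %.0f%%)%s\n", 100 * x$level,
              if (x$degenerate) " [degenerate: point]" else ""))
  cat("center:", paste(sprintf("%s=%.4f", names(x$center), x$center),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Test whether a composition lies inside a confidence region
#'
#' @param region A `"ternary_region"` from [confidence_region()].
#' @param x A 3-part composition (any scale).
#' @return Logical.
#' @export
region_contains <- function(region, x) {
  z <- ilr_transform(close_composition(x, 1), region$partition)
  if (region$degenerate)
    return(all(abs(z - region$center_z) < 1e-8))
  d2 <- stats::mahalanobis(matrix(z, 1L), region$center_z, region$cov_z)
  as.vector(d2 <= region$radius2)
}

# ---- outlier screening -------------------------------------------------

#' Screen paired pre/post compositions for outlying changes via log contrasts
#'
#' For each participant all pairwise logratio change scores
#' `log((post_i/post_j) / (pre_i/pre_j))` are computed (6 scores for 4
#' parts). A participant is flagged when any score's robust z — centred by
#' the cohort median and scaled by the MAD — exceeds `threshold`. Scores
#' are ratio-based, hence invariant to the closure constant. Flagged
#' participants are reported, never dropped silently.
#'
#' @param pre,post Matrices of strictly positive compositions, one aligned
#'   row per participant.
#' @param threshold Robust-z cutoff (default 3.5).
#' @return Logical vector of flags with attributes `scores` (participant x
#'   pair matrix of robust z) and `disabled` (TRUE when the cohort has
#'   fewer than 10 participants and screening is skipped with a warning).
#' @export
flag_outliers <- function(pre, post, threshold = 3.5) {
  prem <- as_comp_matrix(pre)
  postm <- as_comp_matrix(post)
  stopifnot(nrow(prem) == nrow(postm), ncol(prem) == ncol(postm))
  if (any(prem <= 0) || any(postm <= 0))
    stop("outlier screening requires strictly positive compositions")
  n <- nrow(prem)
  if (n < 10L) {
    warning("fewer than 10 participants: outlier screening disabled")
    out <- rep(FALSE, n)
    attr(out, "disabled") <- TRUE
    return(out)
  }
  D <- ncol(prem)
  pairs <- utils::combn(D, 2L)
  nm <- colnames(prem) %||% paste0("part", seq_len(D))
  scores <- matrix(NA_real_, n, ncol(pairs),
                   dimnames = list(rownames(prem),
                                   apply(pairs, 2L, function(p) paste(nm[p], collapse = "/"))))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    s <- log(postm[, i1] / postm[, i2]) - log(prem[, i1] / prem[, i2])
    med <- stats::median(s)
    scale <- stats::mad(s)
    scores[, j] <- if (scale > 1e-8)
      (s - med) / scale
    else  # no spread in the cohort: only genuinely different changes score
      ifelse(abs(s - med) < 1e-6 * (1 + abs(med)), 0, Inf)
  }
  flags <- apply(abs(scores) > threshold, 1L, any)
  attr(flags, "scores") <- scores
  attr(flags, "disabled") <- FALSE
  flags
}
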