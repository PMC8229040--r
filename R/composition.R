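#' @name composition
#' @title Behaviour compositions and the isometric log-ratio transform
#'
#' @description
#' A daily behaviour profile (sitting, standing, stepping minutes) carries
#' only relative information once total waking time is fixed, so the
#' compositional model works on the simplex. These helpers implement
#' closure, sequential-binary-partition (SBP) ILR bases, the ILR transform
#' and its inverse, time reallocation between behaviours, and compositional
#' means. The mathematics is generic in the number of parts; the package
#' default is the three-part (sit, stand, step) composition.
NULL

#' Behaviour part names used throughout the package
#' @keywords internal
.behaviour_parts <- c("sit", "stand", "step")

#' Construct a validated behaviour composition
#'
#' @param sit_min,stand_min,step_min minutes/day in each posture.
#' @param total_min waking wear minutes; defaults to the sum of the parts
#'   and must equal it to within `1e-9` relative tolerance.
#' @return Named numeric vector `c(sit = , stand = , step = )`.
#' @examples
#' behaviour_composition(548, 286, 107)
#' @export
behaviour_composition <- function(sit_min, stand_min, step_min,
                                  total_min = sit_min + stand_min + step_min) {
  parts <- c(sit = sit_min, stand = stand_min, step = step_min)
  if (any(!is.finite(parts)) || any(parts < 0)) {
    stop("behaviour minutes must be finite and nonnegative", call. = FALSE)
  }
  if (abs(sum(parts) - total_min) > 1e-9 * max(1, total_min)) {
    stop("sit + stand + step must equal total_min (got ",
         sum(parts), " vs ", total_min, ")", call. = FALSE)
  }
  parts
}

#' Close a composition to a fixed total
#'
#' Rescales nonnegative parts so they sum to `kappa`, preserving relative
#' information. Closure is idempotent.
#'
#' @param parts numeric vector of at least two nonnegative parts with a
#'   positive sum.
#' @param kappa positive closure constant (default 1). For behaviour
#'   compositions the natural constant is waking wear time, i.e. the sum of
#'   the parts themselves.
#' @return Numeric vector proportional to `parts`, summing to `kappa`.
#' @examples
#' close_composition(c(548, 286, 107))          # proportions
#' close_composition(c(548, 286, 107), 1440)    # scaled to a 24-h day
#' @export
close_composition <- function(parts, kappa = 1) {
  if (length(parts) < 2) stop("need at least two parts", call. = FALSE)
  if (any(!is.finite(parts)) || any(parts < 0)) {
    stop("parts must be finite and nonnegative", call. = FALSE)
  }
  if (sum(parts) <= 0) stop("cannot close an all-zero composition", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be positive", call. = FALSE)
  parts * (kappa / sum(parts))
}

#' Multiplicative zero replacement
#'
#' Replaces zero parts with a small detection-limit value `delta` and
#' shrinks the nonzero parts multiplicatively so the total is preserved.
#' Log-ratio operations refuse zeros by default; this is the opt-in policy
#' for datasets that contain them.
#'
#' @param parts nonnegative numeric vector.
#' @param delta replacement value in the units of `parts` (default 1 min).
#' @return Strictly positive vector with the same sum as `parts`.
#' @export
replace_zeros <- function(parts, delta = 1) {
  zero <- parts == 0
  if (!any(zero)) return(parts)
  total <- sum(parts)
  if (delta * sum(zero) >= total) {
    stop("delta too large for multiplicative zero replacement", call. = FALSE)
  }
  out <- parts * (1 - delta * sum(zero) / total)
  out[zero] <- delta
  out
}

#' Build an orthonormal ILR basis from a sequential binary partition
#'
#' Each column of `sbp` splits the parts still travelling together into a
#' `+1` group of size r and a `-1` group of size s (0 marks parts not
#' involved in that contrast). The corresponding balance row carries
#' `+sqrt(s / (r (r + s)))` on the `+1` parts and `-sqrt(r / (s (r + s)))`
#' on the `-1` parts, which makes the rows of the contrast matrix
#' orthonormal and zero-sum.
#'
#' @param sbp D x (D-1) sign matrix (+1 / -1 / 0), one column per contrast.
#'   Row names, if present, name the parts.
#' @return An object of class `ilr_basis`: a list with elements `sbp`,
#'   `contrast` (the (D-1) x D orthonormal log-contrast matrix) and
#'   `parts`.
#' @examples
#' build_ilr_basis(pivot_sbp())
#' @export
build_ilr_basis <- function(sbp) {
  sbp <- as.matrix(sbp)
  d <- nrow(sbp)
  if (ncol(sbp) != d - 1L) {
    stop("an SBP for ", d, " parts needs ", d - 1L, " contrast columns",
         call. = FALSE)
  }
  if (!all(sbp %in% c(-1, 0, 1))) {
    stop("SBP entries must be -1, 0 or +1", call. = FALSE)
  }
  parts <- rownames(sbp)
  if (is.null(parts)) {
    parts <- if (d == 3L) .behaviour_parts else paste0("part", seq_len(d))
  }
  contrast <- matrix(0, d - 1L, d, dimnames = list(NULL, parts))
  for (j in seq_len(d - 1L)) {
    r <- sum(sbp[, j] == 1)
    s <- sum(sbp[, j] == -1)
    if (r == 0L || s == 0L) {
      stop("SBP column ", j, " must have both a +1 and a -1 group",
           call. = FALSE)
    }
    contrast[j, sbp[, j] == 1]  <-  sqrt(s / (r * (r + s)))
    contrast[j, sbp[, j] == -1] <- -sqrt(r / (s * (r + s)))
  }
  gram <- contrast %*% t(contrast)
  if (max(abs(gram - diag(d - 1L))) > 1e-8) {
    stop("SBP is not a sequential binary partition: ",
         "contrast rows are not orthonormal", call. = FALSE)
  }
  structure(list(sbp = sbp, contrast = contrast, parts = parts),
            class = "ilr_basis")
}

#' Pivot sequential binary partition
#'
#' The package default SBP: contrast j isolates part j against all later
#' parts, so for (sit, stand, step) the balances are sit vs \{stand, step\}
#' and stand vs step. Reallocation estimates downstream are invariant to
#' this choice; a fixed default makes coordinates reproducible.
#'
#' @param parts character vector of part names.
#' @return D x (D-1) sign matrix suitable for [build_ilr_basis()].
#' @export
pivot_sbp <- function(parts = .behaviour_parts) {
  d <- length(parts)
  sbp <- matrix(0, d, d - 1L, dimnames = list(parts, NULL))
  for (j in seq_len(d - 1L)) {
    sbp[j, j] <- 1
    sbp[(j + 1L):d, j] <- -1
  }
  sbp
}

#' @rdname pivot_sbp
#' @export
default_ilr_basis <- function(parts = .behaviour_parts) {
  build_ilr_basis(pivot_sbp(parts))
}

#' @export
print.ilr_basis <- function(x, ...) {
  cat("ILR basis over parts:", paste(x$parts, collapse = ", "), "\n")
  print(round(x$contrast, 6))
  invisible(x)
}

.as_part_matrix <- function(x, basis) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x)) && all(basis$parts %in% colnames(x))) {
    x <- x[, basis$parts, drop = FALSE]
  } else if (ncol(x) != length(basis$parts)) {
    stop("composition has ", ncol(x), " parts; basis expects ",
         length(basis$parts), call. = FALSE)
  }
  x
}

#' Isometric log-ratio transform
#'
#' Maps strictly positive D-part compositions to D-1 real coordinates
#' `z = contrast %*% log(x)`. The transform is invariant to the closure
#' constant, so raw minutes and closed proportions give identical
#' coordinates.
#'
#' @param x a composition (named or basis-ordered numeric vector) or a
#'   matrix / data frame with one composition per row.
#' @param basis an [ilr_basis][build_ilr_basis] (default [default_ilr_basis()]).
#' @return Numeric vector of length D-1, or an n x (D-1) matrix with
#'   columns `z1, z2, ...`.
#' @examples
#' ilr_transform(c(sit = 548, stand = 286, step = 107))
#' @export
ilr_transform <- function(x, basis = default_ilr_basis()) {
  single <- is.null(dim(x)) && !is.data.frame(x)
  m <- .as_part_matrix(x, basis)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("ILR requires strictly positive parts; replace or drop zeros ",
         "first (see replace_zeros() for the multiplicative policy)",
         call. = FALSE)
  }
  z <- log(m) %*% t(basis$contrast)
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  if (single) z[1L, ] else z
}

#' Inverse isometric log-ratio transform
#'
#' @param z coordinate vector (length D-1) or n x (D-1) matrix.
#' @param basis an [ilr_basis][build_ilr_basis].
#' @param kappa closure constant for the returned composition (default 1).
#' @return Composition(s) closed to `kappa`; `inverse_ilr(ilr_transform(x),
#'   kappa = sum(x))` recovers `x`.
#' @export
inverse_ilr <- function(z, basis = default_ilr_basis(), kappa = 1) {
  single <- is.null(dim(z))
  if (single) z <- matrix(z, nrow = 1L)
  if (ncol(z) != nrow(basis$contrast)) {
    stop("z must have ", nrow(basis$contrast), " coordinates", call. = FALSE)
  }
  logx <- z %*% basis$contrast
  logx <- logx - apply(logx, 1L, max)  # overflow guard before exp
  x <- exp(logx)
  x <- x / rowSums(x) * kappa
  colnames(x) <- basis$parts
  if (single) x[1L, ] else x
}

#' Reallocate minutes from one behaviour to another
#'
#' Moves `minutes` from `from_part` to `to_part`, leaving every other part
#' and the total unchanged — the perturbation at the heart of isotemporal
#' substitution. The donor part must retain strictly positive time so
#' log-ratio coordinates stay defined.
#'
#' @param comp named composition vector (minutes).
#' @param from_part,to_part distinct part names present in `comp`.
#' @param minutes positive minutes to move; must be strictly less than
#'   `comp[from_part]`.
#' @return The perturbed composition (same names, same total).
#' @examples
#' reallocate(c(sit = 548, stand = 286, step = 107), "sit", "step", 60)
#' @export
reallocate <- function(comp, from_part, to_part, minutes) {
  if (is.null(names(comp))) names(comp) <- .behaviour_parts[seq_along(comp)]
  for (p in c(from_part, to_part)) {
    if (!p %in% names(comp)) stop("unknown part '", p, "'", call. = FALSE)
  }
  if (from_part == to_part) stop("from_part and to_part must differ", call. = FALSE)
  if (minutes < 0) stop("minutes must be nonnegative", call. = FALSE)
  if (minutes >= comp[[from_part]]) {
    stop("cannot move ", minutes, " min out of '", from_part, "': only ",
         format(comp[[from_part]]), " min available and the part must stay ",
         "positive", call. = FALSE)
  }
  comp[[from_part]] <- comp[[from_part]] - minutes
  comp[[to_part]] <- comp[[to_part]] + minutes
  comp
}

#' Mean behaviour composition of a cohort
#'
#' The compositional (geometric) mean takes per-part `exp(mean(log))` and
#' closes the result to the arithmetic mean total, so it lives at the
#' centre of the Aitchison geometry the CISM model assumes. The arithmetic
#' mean is the per-part average, as printed in descriptive tables.
#'
#' @param rows matrix or data frame of compositions, one per row (columns
#'   named by part, or in basis order).
#' @param method `"geometric"` (default, compositional convention) or
#'   `"arithmetic"`.
#' @return Named composition vector whose total is the mean row total.
#' @export
mean_composition <- function(rows, method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (is.data.frame(rows)) {
    if (all(.behaviour_parts %in% names(rows))) {
      rows <- rows[.behaviour_parts]
    } else if (all(paste0(.behaviour_parts, "_min") %in% names(rows))) {
      rows <- stats::setNames(rows[paste0(.behaviour_parts, "_min")],
                              .behaviour_parts)
    }
    rows <- as.matrix(rows)
  }
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L, dimnames = list(NULL, names(rows)))
  if (nrow(rows) == 0L) stop("no compositions to average", call. = FALSE)
  if (is.null(colnames(rows))) colnames(rows) <- .behaviour_parts[seq_len(ncol(rows))]
  mean_total <- mean(rowSums(rows))
  out <- switch(method,
    arithmetic = colMeans(rows),
    geometric = {
      if (any(rows <= 0)) {
        stop("geometric mean requires strictly positive parts", call. = FALSE)
      }
      close_composition(exp(colMeans(log(rows))), mean_total)
    })
  out
}
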