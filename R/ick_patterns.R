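#' Canonical ICK cysteine-spacing pattern
#'
#' An inhibitor cystine knot (ICK) domain is recognised here purely from its
#' cysteine scaffold: `n_cys` cysteines (6 for the three-disulfide form, 8
#' for the four-disulfide form) whose successive inter-cysteine spacings
#' (residues strictly between consecutive cysteines) each fall within a
#' configurable `(min, max)` bound.
#'
#' The packaged 3-DS default bounds `(3,9) (3,9) (0,7) (1,17) (3,19)` admit
#' the Xt3a domains (spacings 6,6,0,4,10 and 6,6,0,4,9) and typical calcins;
#' the 4-DS default extends them with two short loop-four bounds for the
#' extra stabilising disulfide. Both are fully configurable.
#'
#' @param ds_class `"3DS"` or `"4DS"`.
#' @param loop_bounds Optional `(n_cys - 1) x 2` matrix of `(min, max)`
#'   spacings overriding the packaged defaults.
#' @return An object of class `ick_pattern` with fields `n_cys`, `ds_class`
#'   and `loop_bounds`.
#' @export
ick_pattern <- function(ds_class = c("3DS", "4DS"), loop_bounds = NULL) {
  ds_class <- match.arg(ds_class)
  n_cys <- if (ds_class == "3DS") 6L else 8L
  if (is.null(loop_bounds)) {
    loop_bounds <- if (ds_class == "3DS") {
      rbind(c(3, 9), c(3, 9), c(0, 7), c(1, 17), c(3, 19))
    } else {
      rbind(c(3, 9), c(3, 9), c(0, 7), c(1, 17), c(0, 7), c(0, 7), c(3, 19))
    }
  }
  loop_bounds <- as.matrix(loop_bounds)
  if (nrow(loop_bounds) != n_cys - 1L || ncol(loop_bounds) != 2L) {
    stop("loop_bounds must be a ", n_cys - 1L, " x 2 matrix for ", ds_class)
  }
  if (any(loop_bounds[, 1] > loop_bounds[, 2]) || any(loop_bounds < 0)) {
    stop("each loop bound must satisfy 0 <= min <= max")
  }
  structure(list(n_cys = n_cys, ds_class = ds_class,
                 loop_bounds = loop_bounds),
            class = "ick_pattern")
}

#' @export
print.ick_pattern <- function(x, ...) {
  cat(sprintf("<ick_pattern %s> %d cysteines; loop bounds: %s\n",
              x$ds_class, x$n_cys,
              paste(sprintf("(%g,%g)", x$loop_bounds[, 1], x$loop_bounds[, 2]),
                    collapse = " ")))
  invisible(x)
}

#' Cysteine positions of the Xt3a double-knot scaffold
#'
#' The twelve cysteine positions (1-based) of the 82-residue remipede toxin
#' Xt3a, as implied by its experimentally determined disulfide connectivity.
#'
#' @return Integer vector of length 12.
#' @export
xt3a_cys_positions <- function() {
  c(14L, 21L, 28L, 29L, 34L, 45L, 50L, 57L, 64L, 65L, 70L, 80L)
}

#' Experimentally determined Xt3a disulfide pairs
#'
#' @return A data frame with columns `pos_a`, `pos_b`: the six disulfide
#'   bonds of Xt3a (three per ICK domain).
#' @export
xt3a_disulfides <- function() {
  data.frame(pos_a = c(14L, 21L, 28L, 50L, 57L, 64L),
             pos_b = c(29L, 34L, 45L, 65L, 70L, 80L))
}

#' Synthetic Xt3a cysteine-scaffold fixture
#'
#' An 82-residue record carrying cysteines at the twelve true Xt3a positions.
#' Only the cysteine scaffold is real data; the non-cysteine filler residues
#' are a fixed synthetic sequence (the 19 non-cysteine amino acids cycled in
#' alphabetical order), since downstream scaffold analyses (domain scanning,
#' splitting, connectivity, linker length) depend only on cysteine positions.
#'
#' @return A [seq_record()] with `source = "fixture"`.
#' @export
xt3a_scaffold <- function() {
  len <- 82L
  cys <- xt3a_cys_positions()
  filler <- setdiff(AA_ALPHABET20, "C")
  res <- character(len)
  non_cys <- setdiff(seq_len(len), cys)
  res[non_cys] <- rep_len(filler, length(non_cys))
  res[cys] <- "C"
  seq_record("Xt3a_scaffold", paste(res, collapse = ""),
             description = "synthetic 82-aa scaffold with Xt3a cysteine positions",
             source = "fixture")
}
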