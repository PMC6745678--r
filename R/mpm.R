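#' Projection-matrix record
#'
#' Bundles a per-year projection matrix `A` with its fertility component `F`
#' (same dimension; fertility transitions are a subset of `A`) and a label.
#'
#' @param A Square non-negative numeric matrix.
#' @param F Square non-negative fertility matrix, same dimension as `A`,
#'   elementwise no larger than `A` (tolerance 1e-12).
#' @param label Identifier for the species or population.
#' @param source Free-text provenance.
#' @return An object of class `mpm_record`.
#' @export
mpm_record <- function(A, F, label = "mpm", source = "") {
  A <- as.matrix(A); F <- as.matrix(F)
  if (nrow(A) != ncol(A)) stop("'A' must be square")
  if (!all(dim(F) == dim(A))) stop("'F' must match the dimension of 'A'")
  if (any(A < 0) || any(F < 0)) stop("'A' and 'F' must be non-negative")
  if (any(A - F < -1e-12))
    stop("fertility 'F' exceeds 'A' elementwise; F must be a component of A")
  structure(list(A = A, F = F, label = label, source = source),
            class = "mpm_record")
}

#' @export
print.mpm_record <- function(x, ...) {
  cat(sprintf("<mpm_record '%s': %d x %d>\n", x$label, nrow(x$A), ncol(x$A)))
  invisible(x)
}

#' Dominant eigen-analysis of a projection matrix
#'
#' Dense eigendecomposition returning the dominant eigenvalue with the stable
#' stage distribution `w` (right eigenvector, normalised to sum 1) and the
#' reproductive values `v` (left eigenvector, scaled so `v' w = 1`).
#'
#' @param A Square non-negative matrix. Reducible matrices produce a warning,
#'   not an error.
#' @param imag_tol Tolerance on the imaginary part of the dominant eigenvalue
#'   (relative to its modulus) before the matrix is declared non-primitive.
#' @return List with `lambda_max`, `w`, `v`.
#' @examples
#' eigen_analysis(matrix(c(0, 0.5, 2, 0), 2, 2))
#' @export
eigen_analysis <- function(A, imag_tol = 1e-8) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("'A' must be square")
  if (any(A < 0)) stop("'A' must be non-negative")
  k <- nrow(A)
  if (k == 1L) return(list(lambda_max = A[1, 1], w = 1, v = 1))
  if (is_reducible(A))
    warning("projection matrix appears reducible; dominant eigen-analysis may be degenerate")
  er <- eigen(A)
  # Imprimitive non-negative matrices carry complex eigenvalues of the same
  # modulus as the Perron root; pick the (real, positive) Perron root among
  # the maximal-modulus set rather than an arbitrary member.
  i <- pick_dominant(er$values, imag_tol)
  lam <- er$values[i]
  if (abs(Im(lam)) > imag_tol * max(Mod(lam), 1))
    stop("dominant eigenvalue of matrix is complex beyond tolerance (non-primitive matrix)")
  lam <- Re(lam)
  w <- Re(er$vectors[, i])
  if (sum(w) < 0) w <- -w
  w <- w / sum(w)
  el <- eigen(t(A))
  j <- pick_dominant(el$values, imag_tol)
  v <- Re(el$vectors[, j])
  if (sum(v) < 0) v <- -v
  v <- v / sum(v * w)   # reproductive values scaled so v'w = 1
  list(lambda_max = lam, w = w, v = v)
}

# Index of the dominant eigenvalue: among eigenvalues whose modulus is within
# relative tolerance of the spectral radius, prefer the one with the smallest
# imaginary part (the Perron root of a non-negative matrix is real).
pick_dominant <- function(values, imag_tol) {
  r <- max(Mod(values))
  cand <- which(Mod(values) >= r * (1 - max(imag_tol, 1e-12)))
  im <- abs(Im(values[cand]))
  cand <- cand[im <= min(im) + imag_tol * max(r, 1)]
  cand[which.max(Re(values[cand]))]
}

# Reachability check on the adjacency structure of A: reducible iff the
# digraph is not strongly connected.
is_reducible <- function(A) {
  k <- nrow(A)
  B <- (A > 0) * 1
  R <- diag(k) > 0
  for (i in seq_len(k)) R <- R | ((R %*% B) > 0)
  !all(R & t(R))
}

#' Mean optimal generation time of a projection matrix
#'
#' `T_op = lambda_max * (v' w) / (v' F w)`: the fertility-weighted mean age
#' of mothers at the stable stage distribution. Invariant to any rescaling of
#' `v` and `w`.
#'
#' @param rec An [mpm_record].
#' @return Generation time in years (scalar).
#' @examples
#' rec <- mpm_record(matrix(c(0, 0.5, 2, 0), 2, 2),
#'                   matrix(c(0, 0, 2, 0), 2, 2), "semelparous")
#' generation_time(rec)  # 2
#' @export
generation_time <- function(rec) {
  stopifnot(inherits(rec, "mpm_record"))
  ea <- eigen_analysis(rec$A)
  vFw <- drop(crossprod(ea$v, rec$F %*% ea$w))
  if (vFw <= 0)
    stop(sprintf("zero fertility flow (v'Fw = %g) in '%s': degenerate matrix",
                 vFw, rec$label))
  ea$lambda_max * drop(crossprod(ea$v, ea$w)) / vFw
}

#' Filter projection matrices for demographically optimal conditions
#'
#' Keeps records whose finite growth rate satisfies `lambda_max >= 1` and maps
#' each to its `(r_max = log(lambda_max), T_op)` pair for the allometric
#' regression. Records at exactly `lambda_max = 1` are retained and flagged
#' (`usable = FALSE`): their `r_max` is 0, which the log-log regression cannot
#' accept, so a warning notes their exclusion from fitting.
#'
#' @param records List of [mpm_record] objects.
#' @return Data frame with columns `label`, `lambda_max`, `r_max`, `t_op_bar`,
#'   `usable`.
#' @export
filter_optimal <- function(records) {
  if (length(records) == 0L)
    return(data.frame(label = character(), lambda_max = numeric(),
                      r_max = numeric(), t_op_bar = numeric(),
                      usable = logical()))
  rows <- lapply(records, function(rec) {
    ea <- eigen_analysis(rec$A)
    if (ea$lambda_max < 1) return(NULL)
    data.frame(label = rec$label, lambda_max = ea$lambda_max,
               r_max = log(ea$lambda_max), t_op_bar = generation_time(rec),
               usable = ea$lambda_max > 1)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(label = character(), lambda_max = numeric(),
                      r_max = numeric(), t_op_bar = numeric(),
                      usable = logical()))
  rownames(out) <- NULL
  if (any(!out$usable))
    warning(sum(!out$usable),
            " record(s) with lambda_max = 1 retained but flagged: r_max = 0 ",
            "cannot enter the log-log regression")
  out
}
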