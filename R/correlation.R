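#' Assemble a full correlation target from sparse pairwise entries
#'
#' Builds the square correlation matrix used by the Gaussian copula from a
#' sparse set of published pairwise coefficients, a fill rule for unspecified
#' cells, and a positive-semidefinite repair. Published cells carry their
#' stated values before repair; unspecified cells are filled either with zero
#' or by the anchor-product rule `r_ij = r_iA * r_jA` through an anchor
#' variable A (default `"asm"`), encoding that every measurement co-varies
#' through overall muscularity. The filled matrix is then projected to the
#' nearest valid correlation matrix by iterated eigenvalue clipping at zero
#' with diagonal rescaling.
#'
#' @param printed data.frame of published entries with columns
#'   `var_i`, `var_j`, `r` (see [study_correlation_entries()]).
#' @param fill_rule `"anchor_product"` or `"zero"` for unspecified cells.
#' @param assumed optional data.frame in the same format holding assumed
#'   (non-published) entries, e.g. [study_assumed_correlations()]; recorded
#'   with provenance `"filled"`.
#' @param variables character vector fixing the variable set and order;
#'   defaults to [cohort_variables()] restricted/extended to the variables
#'   appearing in the entries if supplied.
#' @param anchor name of the anchor variable for `fill_rule = "anchor_product"`.
#' @param tol convergence tolerance of the repair iteration.
#' @return An object of class `corr_target`: a list with elements
#'   `matrix` (named square matrix), `provenance` (character matrix with
#'   entries `"printed"`, `"filled"` or `"repaired"`), `printed_deviation`
#'   (max absolute post-repair change on printed cells), `n_clipped`
#'   (eigenvalues clipped) and `fill_rule`.
#' @examples
#' ct <- correlation_target(data.frame(var_i = "a", var_j = "b", r = 0.5),
#'                          fill_rule = "zero", variables = c("a", "b", "c"))
#' ct$matrix
#' @export
correlation_target <- function(printed,
                               fill_rule = c("anchor_product", "zero"),
                               assumed = NULL,
                               variables = NULL,
                               anchor = "asm",
                               tol = 1e-10) {
  fill_rule <- match.arg(fill_rule)
  printed <- as.data.frame(printed)
  stopifnot(all(c("var_i", "var_j", "r") %in% names(printed)))
  entries <- rbind(
    if (nrow(printed)) cbind(printed[c("var_i", "var_j", "r")], src = "printed"),
    if (!is.null(assumed) && nrow(assumed))
      cbind(as.data.frame(assumed)[c("var_i", "var_j", "r")], src = "filled")
  )
  if (is.null(variables)) {
    variables <- cohort_variables()
    seen <- unique(c(entries$var_i, entries$var_j))
    if (!all(seen %in% variables)) variables <- sort(unique(c(variables, seen)))
  }
  if (!is.null(entries)) {
    if (any(abs(entries$r) > 1))
      stop("correlation entries must satisfy |r| <= 1")
    bad <- !(entries$var_i %in% variables) | !(entries$var_j %in% variables)
    if (any(bad))
      stop("entries reference unknown variables: ",
           paste(unique(c(entries$var_i[bad], entries$var_j[bad])), collapse = ", "))
    key <- paste(pmin(entries$var_i, entries$var_j),
                 pmax(entries$var_i, entries$var_j))
    dup <- duplicated(key)
    if (any(dup)) {
      for (k in unique(key[dup])) {
        rs <- entries$r[key == k]
        if (length(unique(rs)) > 1)
          stop("conflicting duplicate correlation entries for pair: ", k)
      }
      entries <- entries[!dup, ]
      key <- key[!dup]
    }
  }

  p <- length(variables)
  R <- diag(p)
  dimnames(R) <- list(variables, variables)
  prov <- matrix("filled", p, p, dimnames = dimnames(R))
  diag(prov) <- "printed"

  # fill pass: anchor products (or zero) everywhere off-diagonal
  if (fill_rule == "anchor_product") {
    a <- setNames(rep(0, p), variables)
    if (anchor %in% variables) a[anchor] <- 1
    if (!is.null(entries)) {
      ai <- entries$var_j == anchor
      a[entries$var_i[ai]] <- entries$r[ai]
      aj <- entries$var_i == anchor
      a[entries$var_j[aj]] <- entries$r[aj]
    }
    R <- outer(a, a)
    diag(R) <- 1
  }

  # stated entries override the fill
  if (!is.null(entries)) {
    for (k in seq_len(nrow(entries))) {
      i <- entries$var_i[k]; j <- entries$var_j[k]
      R[i, j] <- R[j, i] <- entries$r[k]
      prov[i, j] <- prov[j, i] <- entries$src[k]
    }
  }

  pre <- R
  rep_out <- repair_correlation(R, tol = tol)
  delta <- abs(rep_out$matrix - pre)
  prov[delta > 1e-8] <- "repaired"
  printed_mask <- matrix(FALSE, p, p, dimnames = dimnames(prov))
  if (!is.null(entries)) {
    pe <- entries[entries$src == "printed", , drop = FALSE]
    for (k in seq_len(nrow(pe)))
      printed_mask[pe$var_i[k], pe$var_j[k]] <- printed_mask[pe$var_j[k], pe$var_i[k]] <- TRUE
  }
  structure(list(
    matrix = rep_out$matrix,
    provenance = prov,
    printed_deviation = if (any(printed_mask)) max(delta[printed_mask]) else 0,
    n_clipped = rep_out$n_clipped,
    fill_rule = fill_rule
  ), class = "corr_target")
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Iterates eigenvalue clipping at zero followed by diagonal rescaling to unit
#' diagonal until the matrix stops changing. A fixed point of the iteration is
#' positive semidefinite with unit diagonal; valid inputs are returned
#' unchanged.
#'
#' @param R symmetric matrix with unit diagonal and `|entries| <= 1`.
#' @param tol stop when the largest absolute entry change falls below this.
#' @param max_iter iteration cap.
#' @return List with `matrix` (repaired, dimnames preserved) and `n_clipped`
#'   (total eigenvalues clipped over all iterations).
#' @export
repair_correlation <- function(R, tol = 1e-10, max_iter = 500) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-12) stop("matrix must be symmetric")
  dn <- dimnames(R)
  n_clipped <- 0L
  for (it in seq_len(max_iter)) {
    e <- eigen(R, symmetric = TRUE)
    neg <- e$values < 0
    if (!any(e$values < -1e-14)) break
    n_clipped <- n_clipped + sum(neg)
    R2 <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    d <- sqrt(pmax(diag(R2), .Machine$double.eps))
    R2 <- R2 / outer(d, d)
    R2 <- (R2 + t(R2)) / 2
    diag(R2) <- 1
    done <- max(abs(R2 - R)) < tol
    R <- R2
    if (done) break
  }
  dimnames(R) <- dn
  list(matrix = R, n_clipped = n_clipped)
}

#' @export
print.corr_target <- function(x, ...) {
  p <- nrow(x$matrix)
  tab <- table(factor(x$provenance[upper.tri(x$provenance)],
                      levels = c("printed", "filled", "repaired")))
  cat("Correlation target:", p, "variables (", x$fill_rule, "fill )\n")
  cat("  off-diagonal cells:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  max post-repair deviation on printed cells: %.3g\n",
              x$printed_deviation))
  invisible(x)
}

#' Built-in calibrated correlation target for the study cohort
#'
#' Convenience wrapper assembling [study_correlation_entries()] and
#' [study_assumed_correlations()] with the anchor-product fill.
#' @inheritParams correlation_target
#' @return A `corr_target` object over [cohort_variables()].
#' @export
study_correlation_target <- function(fill_rule = "anchor_product") {
  correlation_target(study_correlation_entries(), fill_rule = fill_rule,
                     assumed = study_assumed_correlations(),
                     variables = cohort_variables())
}
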