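## Greedy selection of encoding-spectrum sets.
##
## The objective for a candidate set of M spectra (Eq.-style, literal
## unnormalized form) is
##   O = [sum_n (R R^T)_{n,n}] x [sum_n int_{outside interval n} SRF_n^2]
## i.e. total noise amplification times total out-of-interval SRF power.
## With A = (E^T E)^-1 the noise term is trace(A), and the contamination
## term reduces to quadratic forms in per-interval Gram matrices
## G_j[m,m'] = int_j P_m P_m' domega, which are precomputed once per
## library/scheme ("gram cache") so that greedy sweeps over hundreds of
## members stay cheap. Candidate updates use rank-one Sherman-Morrison
## downdates of A and rank-two downdates of the projected Gram forms.

#' Precompute the interval quadrature cache for a library
#'
#' @param library a `tds_library`
#' @param scheme a `tds_scheme`
#' @return an object of class `tds_gram_cache`: `E` (M x N interval
#'   coefficient table), `G` (list of N M x M interval Gram matrices),
#'   `cutoff` (rad/s), `W` (quadrature weights)
#' @export
gram_cache <- function(library, scheme) {
  stopifnot(inherits(library, "tds_library"), inherits(scheme, "tds_scheme"))
  cutoff <- resolve_tail_cutoff(scheme, library$omega, library$power)
  W <- scheme_weights(library$omega, scheme, cutoff)
  P <- library$power
  E <- crossprod(P, W) / pi                    # M x N
  G <- lapply(seq_len(ncol(W)), function(j) crossprod(P, P * W[, j]))
  structure(list(E = E, G = G, cutoff = cutoff, W = W, scheme = scheme),
            class = "tds_gram_cache")
}

## Objective for subset idx given projected quantities. A is (E^T E)^-1 (or
## (E E^T)^-1-based right-pseudoinverse path when M < N). H[[j]] is the N x N
## projection  E_sub^T G_j[sub,sub] E_sub.
.obj_from_AH <- function(A, H) {
  noise <- sum(diag(A))
  contam <- 0
  for (j in seq_along(H)) {
    B <- A %*% H[[j]] %*% A
    contam <- contam + sum(diag(B)) - B[j, j]
  }
  c(objective = noise * contam, noise = noise, contamination = contam)
}

#' Evaluate the selection objective for a set of library members
#'
#' Returns the product objective together with its noise and contamination
#' factors. For fewer members than intervals (`M < N`, only meaningful while
#' growing a selection) the minimum-norm right pseudoinverse is used, and
#' the objective is `+Inf` if any interval carries (numerically) no encoding
#' power or the system is ill-conditioned.
#'
#' @param idx integer vector of member indices
#' @param library a `tds_library`
#' @param scheme a `tds_scheme`
#' @param cache optional `tds_gram_cache` (built on the fly if missing)
#' @return named numeric vector `(objective, noise, contamination)`
#' @export
encoding_objective <- function(idx, library, scheme, cache = NULL) {
  if (is.null(cache)) cache <- gram_cache(library, scheme)
  E <- cache$E[idx, , drop = FALSE]
  N <- ncol(E); M <- nrow(E)
  if (M >= N) {
    EtE <- crossprod(E)
    if (rcond(EtE) < 1e-16)
      return(c(objective = Inf, noise = Inf, contamination = Inf))
    A <- solve(EtE)
    R <- A %*% t(E)
  } else {
    if (any(colSums(E) <= 0))
      return(c(objective = Inf, noise = Inf, contamination = Inf))
    EEt <- tcrossprod(E)
    if (rcond(EEt) < 1e-12)
      return(c(objective = Inf, noise = Inf, contamination = Inf))
    R <- t(E) %*% solve(EEt)                  # N x M minimum-norm
  }
  noise <- sum(rowSums(R^2))                  # trace(R R^T)
  contam <- 0
  for (j in seq_along(cache$G)) {
    Gs <- cache$G[[j]][idx, idx, drop = FALSE]
    Bj <- R %*% Gs %*% t(R)
    contam <- contam + sum(diag(Bj)) - Bj[j, j]
  }
  c(objective = noise * contam, noise = noise, contamination = contam)
}

## assemble a SelectionResult structure
.selection_result <- function(variant, sets, scores, library) {
  trace <- do.call(rbind, lapply(seq_along(sets), function(i) {
    data.frame(M = length(sets[[i]]), objective = scores[[i]]["objective"],
               noise = scores[[i]]["noise"],
               contamination = scores[[i]]["contamination"],
               variant = variant)
  }))
  rownames(trace) <- NULL
  structure(list(variant = variant, sets = sets, trace = trace,
                 members = library$members),
            class = "tds_selection")
}

#' @export
print.tds_selection <- function(x, ...) {
  cat(sprintf("<tds_selection> variant=%s, M = %s\n", x$variant,
              paste(range(x$trace$M), collapse = "..")))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Retrieve the selected member indices for a given M
#' @param sel a `tds_selection`
#' @param M number of measurements
#' @return integer vector of member indices
#' @export
selected_set <- function(sel, M) {
  hit <- which(vapply(sel$sets, length, integer(1)) == M)
  if (length(hit) == 0) stop("no selection recorded for M = ", M)
  sel$sets[[hit[1]]]
}

#' Greedy pruning of the spectrum library
#'
#' Starting from the full library, each iteration removes the member whose
#' exclusion minimizes the objective, until N members remain. Ties are
#' broken toward removing the lowest member index. Within one run the
#' selected sets are nested across M.
#'
#' @param library a `tds_library`
#' @param scheme a `tds_scheme`
#' @param cache optional `tds_gram_cache`
#' @param m_min smallest set size to descend to (default N)
#' @param verbose print per-iteration progress
#' @return a `tds_selection` (variant `"prune"`) with one entry per M from
#'   `library_size(library)` down to `m_min`
#' @export
greedy_prune <- function(library, scheme, cache = NULL,
                         m_min = scheme$n_intervals, verbose = FALSE) {
  if (is.null(cache)) cache <- gram_cache(library, scheme)
  Mlib <- nrow(cache$E)
  N <- scheme$n_intervals
  if (m_min < N) stop("cannot prune below N = ", N, " members")
  if (Mlib < m_min) stop("library smaller than the requested set size")
  idx <- seq_len(Mlib)
  sets <- list(idx)
  scores <- list(encoding_objective(idx, library, scheme, cache))
  while (length(idx) > m_min) {
    best <- .prune_step(idx, cache)
    idx <- setdiff(idx, best$remove)
    sets[[length(sets) + 1L]] <- idx
    scores[[length(scores) + 1L]] <- best$score
    if (verbose)
      message(sprintf("prune -> M=%d objective=%.4g", length(idx),
                      best$score["objective"]))
  }
  .selection_result("prune", sets, scores, library)
}

## One pruning sweep: evaluate removal of each member of idx, return the
## member whose removal minimizes the objective (ties: lowest member index).
.prune_step <- function(idx, cache) {
  E <- cache$E[idx, , drop = FALSE]
  M <- nrow(E); N <- ncol(E)
  EtE <- crossprod(E)
  ok_base <- rcond(EtE) > 1e-16
  A <- if (ok_base) solve(EtE) else NULL
  Gs <- lapply(cache$G, function(g) g[idx, idx, drop = FALSE])
  W <- lapply(Gs, function(g) crossprod(E, g))  # N x M, W_j = E^T G_j
  H <- lapply(seq_len(N), function(j) W[[j]] %*% E)
  best_obj <- Inf; best_k <- NA_integer_; best_score <- NULL
  for (k in seq_len(M)) {
    ek <- E[k, ]
    score <- if (ok_base) {
      u <- A %*% ek
      denom <- 1 - sum(ek * u)
      if (abs(denom) < 1e-12) {
        NULL
      } else {
        Ak <- A + tcrossprod(u) / denom
        Hk <- lapply(seq_len(N), function(j) {
          wk <- W[[j]][, k]
          H[[j]] - tcrossprod(ek, wk) - tcrossprod(wk, ek) +
            Gs[[j]][k, k] * tcrossprod(ek)
        })
        .obj_from_AH(Ak, Hk)
      }
    } else NULL
    if (is.null(score)) {
      ## fall back to direct evaluation (near-singular downdate)
      sub <- idx[-k]
      score <- encoding_objective(sub, NULL, cache$scheme, cache)
    }
    if (is.finite(score["objective"]) && score["objective"] < best_obj) {
      best_obj <- score["objective"]; best_k <- k; best_score <- score
    }
  }
  if (is.na(best_k))
    stop("pruning failed: every reduced set is rank-deficient")
  list(remove = idx[best_k], score = best_score)
}

#' Greedy growth of an encoding set
#'
#' The first iteration exhaustively scores all member pairs; each subsequent
#' iteration adds the single member that minimizes the objective. For
#' M < N the objective is evaluated on the rank-supported subspace via the
#' minimum-norm right pseudoinverse (see [encoding_objective()]).
#'
#' @param library a `tds_library`
#' @param scheme a `tds_scheme`
#' @param cache optional `tds_gram_cache`
#' @param m_max largest set size to grow to
#' @param verbose print per-iteration progress
#' @return a `tds_selection` (variant `"grow"`) with one entry per M from 2
#'   to `m_max`
#' @export
greedy_grow <- function(library, scheme, cache = NULL,
                        m_max = scheme$n_intervals + 6L, verbose = FALSE) {
  if (is.null(cache)) cache <- gram_cache(library, scheme)
  Mlib <- nrow(cache$E)
  if (Mlib < 2) stop("library must contain at least two members")
  m_max <- min(m_max, Mlib)
  pair <- .best_pair(cache)
  idx <- pair$idx
  sets <- list(idx)
  scores <- list(pair$score)
  while (length(idx) < m_max) {
    rest <- setdiff(seq_len(Mlib), idx)
    best_obj <- Inf; best_c <- NA_integer_; best_score <- NULL
    for (cnd in rest) {
      score <- encoding_objective(c(idx, cnd), NULL, cache$scheme, cache)
      if (is.finite(score["objective"]) && score["objective"] < best_obj) {
        best_obj <- score["objective"]; best_c <- cnd; best_score <- score
      }
    }
    if (is.na(best_c)) {
      ## all additions rank-deficient (cannot happen once M >= N); take
      ## lowest-index member to keep the run total
      best_c <- rest[1]
      best_score <- encoding_objective(c(idx, best_c), NULL, cache$scheme,
                                       cache)
    }
    idx <- sort(c(idx, best_c))
    sets[[length(sets) + 1L]] <- idx
    scores[[length(scores) + 1L]] <- best_score
    if (verbose)
      message(sprintf("grow -> M=%d objective=%.4g", length(idx),
                      best_score["objective"]))
  }
  .selection_result("grow", sets, scores, library)
}

## exhaustive search over all member pairs (M = 2 scoring path)
.best_pair <- function(cache) {
  Mlib <- nrow(cache$E)
  best_obj <- Inf; best <- NULL; best_score <- NULL
  for (a in seq_len(Mlib - 1L)) for (b in (a + 1L):Mlib) {
    score <- encoding_objective(c(a, b), NULL, cache$scheme, cache)
    if (is.finite(score["objective"]) && score["objective"] < best_obj) {
      best_obj <- score["objective"]; best <- c(a, b); best_score <- score
    }
  }
  if (is.null(best)) stop("no feasible pair: all pairs are rank-deficient")
  list(idx = best, score = best_score)
}

#' Combine prune and grow selections per M
#'
#' For every M present in both runs, keeps the set with the lower objective
#' (the prune result wins exact ties).
#'
#' @param prune a `tds_selection` from [greedy_prune()]
#' @param grow a `tds_selection` from [greedy_grow()]
#' @return a `tds_selection` (variant `"best"`) whose trace records the
#'   winning variant per M
#' @export
select_best <- function(prune, grow) {
  stopifnot(inherits(prune, "tds_selection"), inherits(grow, "tds_selection"))
  ms <- sort(intersect(prune$trace$M, grow$trace$M))
  sets <- list(); rows <- list()
  for (i in seq_along(ms)) {
    M <- ms[i]
    rp <- prune$trace[prune$trace$M == M, ][1, ]
    rg <- grow$trace[grow$trace$M == M, ][1, ]
    take_grow <- is.finite(rg$objective) &&
      (!is.finite(rp$objective) || rg$objective < rp$objective)
    src <- if (take_grow) grow else prune
    row <- if (take_grow) rg else rp
    row$variant <- if (take_grow) "grow" else "prune"
    sets[[i]] <- selected_set(src, M)
    rows[[i]] <- row
  }
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  structure(list(variant = "best", sets = sets, trace = trace,
                 members = prune$members),
            class = "tds_selection")
}

#' Build an encoding system from selected library members
#' @param library a `tds_library`
#' @param idx member indices (e.g. from [selected_set()])
#' @param scheme a `tds_scheme`
#' @return a `tds_system`
#' @export
system_from_library <- function(library, idx, scheme) {
  build_system(library$spectra[idx], scheme)
}
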