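# Phylogenetic likelihood under JTT(+I)(+Gamma): Felsenstein pruning over
# compressed site patterns (gaps as missing data), per-branch Brent
# optimisation on cached edge flows, NNI hill-climbing, and AIC model
# ranking.

# compress alignment columns (restricted to the tree's tips, tip order) into
# site patterns with weights and per-pattern constant-state bookkeeping
prep_patterns <- function(msa, tips, weights = NULL) {
  msa <- as_protein_msa(msa)
  missing <- setdiff(tips, msa$ids)
  if (length(missing)) {
    abort(paste0("tree tips absent from alignment: ",
                 paste(missing, collapse = ", ")))
  }
  st <- msa_state_matrix(msa, tips)
  w <- weights %||% rep(1, ncol(st))
  keep <- w > 0
  st <- st[, keep, drop = FALSE]
  w <- w[keep]
  keys <- apply(st, 2, paste, collapse = ",")
  first <- !duplicated(keys)
  pat <- st[, first, drop = FALSE]
  patw <- as.numeric(tapply(w, factor(keys, keys[first]), sum))
  conststate <- apply(pat, 2, function(col) {
    obs <- unique(col[col >= 0L])
    if (!length(obs)) -2L else if (length(obs) == 1L) obs else -1L
  })
  list(states = pat, weights = patw, conststate = as.integer(conststate),
       n_sites = sum(w))
}

pconst_of <- function(conststate, model) {
  pc <- numeric(length(conststate))
  pc[conststate == -2L] <- 1
  idx <- conststate >= 0L
  pc[idx] <- model$pi[conststate[idx] + 1L]
  pc
}

#' Phylogenetic log-likelihood (Felsenstein pruning)
#'
#' Per-site likelihood `p_inv * [constant ? pi_residue : 0] +
#' (1 - p_inv) * mean_k L(rate r_k)` with discrete-gamma category rates;
#' gap characters are missing data (all-ones tip vectors).
#'
#' @param tree `ape::phylo` with branch lengths (tips must be in the
#'   alignment)
#' @param msa a `protein_msa`
#' @param model an [jtt_model()]
#' @param weights optional column weights (bootstrap reweighting)
#' @return the log-likelihood; per-pattern values in attribute
#'   `"site_loglik"`
#' @export
log_likelihood <- function(tree, msa, model = jtt_model(), weights = NULL) {
  msa <- as_protein_msa(msa)
  if (length(tree$tip.label) == 1L) {
    # degenerate single-sequence case
    st <- aa_states(msa$seqs[[tree$tip.label]])
    pc <- ifelse(is.na(st), 1, model$pi[st + 1L])
    site <- log(model$p_inv * ifelse(is.na(st), 1, pc) +
                  (1 - model$p_inv) * pc)
    return(structure(sum(site), site_loglik = site))
  }
  if (is.null(tree$edge.length)) abort("tree needs branch lengths")
  if (any(tree$edge.length < 0)) abort("branch lengths must be >= 0")
  pd <- prep_patterns(msa, tree$tip.label, weights)
  phy <- as_postorder(tree)
  res <- cpp_tree_loglik(
    phy$edge, phy$edge.length, length(phy$tip.label), pd$states, pd$weights,
    model$pi, model$eig$V, model$eig$lambda, model$eig$Vinv,
    model$rates, model$cat_weights, model$p_inv, pd$conststate
  )
  structure(res$loglik, site_loglik = res$site_loglik)
}

# one flows computation for the current tree (postorder)
edge_flows <- function(phy, pd, model) {
  cpp_edge_flows(phy$edge, phy$edge.length, length(phy$tip.label),
                 pd$states, model$pi, model$eig$V, model$eig$lambda,
                 model$eig$Vinv, model$rates)
}

tree_ll <- function(phy, pd, model) {
  cpp_tree_loglik(phy$edge, phy$edge.length, length(phy$tip.label),
                  pd$states, pd$weights, model$pi, model$eig$V,
                  model$eig$lambda, model$eig$Vinv, model$rates,
                  model$cat_weights, model$p_inv, pd$conststate)$loglik
}

#' Optimise branch lengths by per-branch Brent updates
#'
#' Sweeps over all branches, each optimised by Brent's method on cached
#' conditional-likelihood flows; a sweep is accepted only when the full
#' log-likelihood improves (falling back to freshly recomputed flows per
#' branch otherwise).
#'
#' @inheritParams log_likelihood
#' @param max_sweeps maximum number of sweeps
#' @param tol convergence tolerance on the log-likelihood between sweeps
#' @return list with `tree` (branch lengths updated, postorder) and
#'   `loglik`
#' @export
optimize_branch_lengths <- function(tree, msa, model = jtt_model(),
                                    weights = NULL, max_sweeps = 5L,
                                    tol = 1e-4, patterns = NULL) {
  pd <- patterns %||% prep_patterns(as_protein_msa(msa), tree$tip.label,
                                    weights)
  phy <- as_postorder(tree)
  npat <- ncol(pd$states)
  ncat <- model$n_categories
  pc <- pconst_of(pd$conststate, model)
  ll <- tree_ll(phy, pd, model)
  nedge <- nrow(phy$edge)
  for (sweep in seq_len(max_sweeps)) {
    fl <- edge_flows(phy, pd, model)
    cand <- phy$edge.length
    for (e in seq_len(nedge)) {
      f <- function(t) {
        cpp_edge_loglik(fl$Z, fl$ls, e - 1L, npat, ncat, pd$weights,
                        model$eig$lambda, model$rates, model$cat_weights,
                        model$p_inv, pc, t)
      }
      cand[e] <- optimize(f, c(0, 10), maximum = TRUE, tol = 1e-6)$maximum
    }
    old <- phy$edge.length
    phy$edge.length <- cand
    ll_new <- tree_ll(phy, pd, model)
    if (ll_new < ll) {
      # stale-flow sweep failed; redo one branch at a time with fresh flows
      phy$edge.length <- old
      ll_new <- ll
      for (e in seq_len(nedge)) {
        fl <- edge_flows(phy, pd, model)
        f <- function(t) {
          cpp_edge_loglik(fl$Z, fl$ls, e - 1L, npat, ncat, pd$weights,
                          model$eig$lambda, model$rates, model$cat_weights,
                          model$p_inv, pc, t)
        }
        opt <- optimize(f, c(0, 10), maximum = TRUE, tol = 1e-6)
        cur <- f(phy$edge.length[e])
        if (opt$objective > cur) phy$edge.length[e] <- opt$maximum
      }
      ll_new <- tree_ll(phy, pd, model)
    }
    done <- (ll_new - ll) < tol
    ll <- ll_new
    if (done) break
  }
  list(tree = phy, loglik = ll)
}

# internal edges eligible for NNI (child node internal)
nni_edges <- function(phy) {
  ntip <- length(phy$tip.label)
  which(phy$edge[, 2] > ntip)
}

# the two NNI rearrangements around an internal edge: swap each child
# subtree of the edge's lower node with one subtree on the other side
nni_neighbors <- function(phy, e) {
  u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
  vkids <- which(phy$edge[, 1] == v)
  ukids <- setdiff(which(phy$edge[, 1] == u), e)
  if (!length(vkids) || !length(ukids)) return(list())
  s <- ukids[1]
  lapply(vkids[1:2], function(ck) {
    tr <- phy
    tmp <- tr$edge[ck, 2]
    tr$edge[ck, 2] <- tr$edge[s, 2]
    tr$edge[s, 2] <- tmp
    as_postorder(tr)
  })
}

#' Nearest-neighbor-interchange search
#'
#' Hill-climbing over NNI neighborhoods. Candidate rearrangements are
#' screened at current branch lengths; those within `screen_margin`
#' log-units of the incumbent are refined by branch-length re-optimisation,
#' and a move is accepted when it improves the log-likelihood by more than
#' `tol`. Terminates at a local optimum or after `max_rounds`.
#'
#' @param start starting tree (bifurcating, branch lengths optional)
#' @inheritParams log_likelihood
#' @param max_rounds maximum accepted moves
#' @param screen_margin log-likelihood screening window for candidate
#'   refinement
#' @param tol acceptance threshold on the log-likelihood improvement
#' @return an object of class `ml_fit`: `tree`, `loglik`, `model`, `trace`
#' @export
nni_search <- function(start, msa, model = jtt_model(), weights = NULL,
                       max_rounds = 10L, screen_margin = 5, tol = 1e-8,
                       sweeps = 5L, patterns = NULL) {
  msa <- as_protein_msa(msa)
  if (is.null(start$edge.length)) {
    start$edge.length <- rep(0.1, nrow(start$edge))
  }
  # NNI operates on the unrooted topology; a rooted start has a degenerate
  # root edge around which no rearrangement changes the tree
  if (ape::is.rooted(start) && length(start$tip.label) > 3L) {
    start <- ape::unroot(start)
  }
  pd <- patterns %||% prep_patterns(msa, start$tip.label, weights)
  fit <- optimize_branch_lengths(start, msa, model, max_sweeps = sweeps,
                                 patterns = pd)
  phy <- fit$tree
  ll <- fit$loglik
  trace <- list(tibble(round = 0L, loglik = ll, move = "start"))
  for (round in seq_len(max_rounds)) {
    best_ll <- ll
    best_tree <- NULL
    sc <- cpp_nni_screen(
      phy$edge, phy$edge.length, length(phy$tip.label), pd$states,
      pd$weights, model$pi, model$eig$V, model$eig$lambda, model$eig$Vinv,
      model$rates, model$cat_weights, model$p_inv, pd$conststate
    )
    for (q in order(sc$loglik, decreasing = TRUE)) {
      if (sc$loglik[q] <= ll - screen_margin) break
      cand <- phy
      ck <- sc$child_row[q]; s <- sc$sib_row[q]
      tmp <- cand$edge[ck, 2]
      cand$edge[ck, 2] <- cand$edge[s, 2]
      cand$edge[s, 2] <- tmp
      cand <- as_postorder(cand)
      ref <- optimize_branch_lengths(cand, msa, model,
                                     max_sweeps = 2L, patterns = pd)
      if (ref$loglik > best_ll + tol) {
        best_ll <- ref$loglik
        best_tree <- ref$tree
      }
    }
    if (is.null(best_tree)) break
    phy <- best_tree
    ll <- best_ll
    trace <- c(trace, list(tibble(round = round, loglik = ll, move = "NNI")))
  }
  structure(
    list(tree = phy, loglik = ll, model = model, trace = bind_rows(trace),
         n_patterns = ncol(pd$states), n_sites = pd$n_sites),
    class = "ml_fit"
  )
}

#' Maximum-likelihood tree
#'
#' Neighbor-joining starting tree on ML distances, branch-length
#' optimisation and NNI search.
#'
#' @inheritParams log_likelihood
#' @param start optional starting tree (default: NJ on plain-JTT distances)
#' @param ... passed to [nni_search()]
#' @return an `ml_fit`
#' @export
ml_tree <- function(msa, model = jtt_model(), start = NULL, weights = NULL,
                    ...) {
  msa <- as_protein_msa(msa)
  if (is.null(start)) {
    D <- protein_distance_matrix(msa, jtt_model(), weights = weights)
    start <- neighbor_joining(D)
  }
  nni_search(start, msa, model, weights, ...)
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("ML fit (", x$model$name, "): lnL =", format(x$loglik, digits = 10),
      "on", x$n_sites, "sites (", x$n_patterns, "patterns )\n")
  invisible(x)
}

# golden-section maximisation on [lo, hi]
golden_max <- function(f, lo, hi, tol = 1e-3, maxit = 60L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(maxit)) {
    if (abs(b - a) < tol) break
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  if (f1 > f2) list(maximum = x1, objective = f1)
  else list(maximum = x2, objective = f2)
}

# joint estimation of alpha (golden on log scale over [0.05, 10]) and p_inv
# (golden over [0, 0.8]) on a fixed tree
fit_rate_parameters <- function(tree, msa, gamma, inv, n_categories = 4L,
                                cycles = 2L) {
  msa <- as_protein_msa(msa)
  pd <- prep_patterns(msa, tree$tip.label)
  phy <- as_postorder(tree)
  alpha <- if (gamma) 1 else NULL
  pinv <- if (inv) 0.2 else 0
  obj <- function(a, p) {
    m <- jtt_model(p_inv = p, alpha = a, n_categories = n_categories)
    tree_ll(phy, pd, m)
  }
  for (cy in seq_len(cycles)) {
    if (gamma) {
      g <- golden_max(function(la) obj(exp(la), pinv),
                      log(0.05), log(10), tol = 1e-3)
      alpha <- exp(g$maximum)
    }
    if (inv) {
      g <- golden_max(function(p) obj(alpha, p), 0, 0.8, tol = 1e-4)
      pinv <- g$maximum
    }
  }
  list(alpha = alpha, p_inv = pinv,
       model = jtt_model(p_inv = pinv, alpha = alpha,
                         n_categories = n_categories))
}

#' AIC ranking of substitution models on a fixed topology
#'
#' Fits each candidate (branch lengths re-optimised; `alpha` and `p_inv`
#' estimated where the candidate includes them), then ranks by
#' `AIC = 2k - 2 lnL` with `k` counting branch lengths plus model
#' parameters. Identical candidate specifications are deduplicated before
#' ranking, so a duplicated single candidate reports `dAIC = 0` and weight
#' 1. Akaike weights are `exp(-d_i/2) / sum_j exp(-d_j/2)`.
#'
#' @param msa a `protein_msa`
#' @param tree evaluation topology with branch lengths
#' @param models candidate names among `"JTT"`, `"JTT+G"`, `"JTT+I"`,
#'   `"JTT+I+G"`
#' @param n_categories gamma categories
#' @return tibble with `model`, `loglik`, `k`, `AIC`, `delta_AIC`,
#'   `weight`, `ok`
#' @export
aic_select <- function(msa, tree,
                       models = c("JTT", "JTT+G", "JTT+I", "JTT+I+G"),
                       n_categories = 4L) {
  known <- c("JTT", "JTT+G", "JTT+I", "JTT+I+G")
  bad <- setdiff(models, known)
  if (length(bad)) {
    abort(paste0("unknown model(s): ", paste(bad, collapse = ", ")))
  }
  models <- unique(models)
  msa <- as_protein_msa(msa)
  nedge <- nrow(tree$edge)
  rows <- purrr::map(models, function(name) {
    gamma <- grepl("G", name, fixed = TRUE)
    inv <- grepl("I", name, fixed = TRUE)
    res <- tryCatch({
      fitp <- fit_rate_parameters(tree, msa, gamma, inv, n_categories)
      bo <- optimize_branch_lengths(tree, msa, fitp$model, max_sweeps = 3L)
      fitp2 <- fit_rate_parameters(bo$tree, msa, gamma, inv, n_categories,
                                   cycles = 1L)
      bo2 <- optimize_branch_lengths(bo$tree, msa, fitp2$model,
                                     max_sweeps = 2L)
      list(loglik = bo2$loglik, ok = TRUE)
    }, error = function(e) list(loglik = NA_real_, ok = FALSE))
    k <- nedge + gamma + inv
    tibble(model = name, loglik = res$loglik, k = k,
           AIC = 2 * k - 2 * res$loglik, ok = res$ok)
  })
  out <- bind_rows(rows)
  best <- min(out$AIC[out$ok], na.rm = TRUE)
  out <- out |>
    mutate(delta_AIC = .data$AIC - best) |>
    mutate(weight = exp(-.data$delta_AIC / 2)) |>
    mutate(weight = dplyr::if_else(.data$ok, .data$weight, NA_real_)) |>
    mutate(weight = .data$weight / sum(.data$weight, na.rm = TRUE)) |>
    arrange(.data$AIC)
  out
}
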