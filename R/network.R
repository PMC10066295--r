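## Wagner-style Boolean threshold gene regulatory network model.
##
## Genes carry expression states in {-1, +1} (off/on); deleted genes are
## coded 0 and frozen. Dynamics are the synchronous difference equation
## S_i(t+1) = sigma(sum_j w_ij S_j(t)) with sigma the sign function and
## sigma(0) = +1 by convention. Phenotypes are stable fixed points.

#' Sign threshold with a fixed tie convention
#'
#' The update nonlinearity of the threshold network: \code{-1} for negative
#' arguments, \code{+1} for positive ones, and \code{+1} at exactly zero.
#' Ties are measure-zero for dense Gaussian weights but do occur with sparse
#' masks and deletions; fixing \code{sigma(0) = +1} keeps runs deterministic.
#'
#' @param x Numeric vector; must be finite.
#' @return Integer vector of -1 / +1, same length as `x`.
#' @examples
#' sign_threshold(c(-0.5, 0, 3.2))
#' @export
sign_threshold <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("sign_threshold() requires finite numeric input")
  }
  ifelse(x < 0, -1L, 1L)
}

#' Draw a random expression state
#'
#' Each gene is independently on (+1) or off (-1) with probability 1/2.
#' Consumes exactly `n` uniform deviates from R's RNG stream.
#'
#' @param n Number of genes (>= 1).
#' @return Integer vector of length `n` over \{-1, +1\}.
#' @examples
#' set.seed(1); sample_state(4)
#' @export
sample_state <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("sample_state() requires n >= 1")
  }
  ifelse(stats::runif(n) < 0.5, 1L, -1L)
}

#' Construct a regulatory network object
#'
#' @param weights Square numeric weight matrix (`w[i, j]` is the effect of
#'   gene `j` on gene `i`).
#' @param connectivity Nominal fraction of nonzero entries `c` in (0, 1].
#' @param topology Character label, `"dense"` or `"modular"`.
#' @return A `regulatory_network`: list with `weights`, `n_genes`,
#'   `connectivity`, `topology`.
#' @export
regulatory_network <- function(weights, connectivity = NA_real_,
                               topology = "dense") {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weight matrix must be square")
  structure(list(weights = weights, n_genes = nrow(weights),
                 connectivity = connectivity, topology = topology),
            class = "regulatory_network")
}

## Accept either a regulatory_network or a bare matrix.
as_weights <- function(network) {
  if (inherits(network, "regulatory_network")) network$weights
  else as.matrix(network)
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("Regulatory network: N = %d genes, topology = %s, c = %s\n",
              x$n_genes, x$topology,
              format(x$connectivity, digits = 3)))
  cat(sprintf("Realized nonzero fraction: %.3f\n",
              mean(x$weights != 0)))
  invisible(x)
}

#' Sample a random weight matrix
#'
#' Dense mode: every entry is nonzero independently with probability `c`
#' (including the diagonal) and nonzero values are standard normal, so the
#' realized connectivity is binomially distributed around `c`. Modular mode:
#' a binary adjacency from [sample_modular_adjacency()] is scaled entrywise
#' by standard-normal weights.
#'
#' Draw order (relevant for replaying the RNG stream): `n^2` normals filled
#' column-major, then — only when `c < 1` — `n^2` uniforms for the mask.
#' With `exact_count = TRUE` the mask instead places exactly
#' `round(c * n^2)` nonzero entries chosen uniformly at random.
#'
#' @param n Number of genes.
#' @param c Connectivity in (0, 1]. Ignored in modular mode.
#' @param topology `"dense"` (default) or `"modular"`.
#' @param module_count,overlap,p_in,p_out Passed to
#'   [sample_modular_adjacency()] when `topology = "modular"`.
#' @param exact_count Use an exact-count connectivity mask instead of
#'   independent Bernoulli(c) entries.
#' @return A [regulatory_network()].
#' @examples
#' set.seed(1); sample_network(10, 1)
#' @export
sample_network <- function(n, c = 1, topology = c("dense", "modular"),
                           module_count = 2, overlap = 0,
                           p_in = 0.8, p_out = 0.05,
                           exact_count = FALSE) {
  topology <- match.arg(topology)
  if (!is.numeric(c) || length(c) != 1L || c <= 0 || c > 1) {
    stop("connectivity c must lie in (0, 1]")
  }
  if (n < 1) stop("n must be >= 1")
  if (topology == "modular") {
    adj <- sample_modular_adjacency(n, module_count, overlap, p_in, p_out)
    w <- adj * matrix(stats::rnorm(n * n), n, n)
    return(regulatory_network(w, connectivity = mean(adj != 0),
                              topology = "modular"))
  }
  w <- matrix(stats::rnorm(n * n), n, n)
  if (c < 1) {
    if (exact_count) {
      keep <- sample.int(n * n, round(c * n * n))
      mask <- logical(n * n); mask[keep] <- TRUE
      w[!mask] <- 0
    } else {
      w[matrix(stats::runif(n * n), n, n) >= c] <- 0
    }
  }
  regulatory_network(w, connectivity = c, topology = "dense")
}

#' Sample a modular random adjacency matrix
#'
#' Stand-in generator for network topologies that mimic empirical gene
#' interaction networks: genes are partitioned into `module_count` modules of
#' near-equal size (optionally with overlapping membership), and directed
#' edges are present with probability `p_in` when the two genes share a
#' module and `p_out` otherwise. No symmetry is imposed.
#'
#' @param n Number of genes.
#' @param module_count Number of modules, between 1 and `n`.
#' @param overlap Fraction of genes granted membership in a second module.
#' @param p_in,p_out Within-/between-module edge probabilities.
#' @return Binary `n` x `n` matrix.
#' @export
sample_modular_adjacency <- function(n, module_count, overlap = 0,
                                     p_in = 0.8, p_out = 0.05) {
  if (module_count < 1 || module_count > n) {
    stop("module_count must lie in [1, n]")
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  membership <- matrix(FALSE, n, module_count)
  primary <- rep_len(seq_len(module_count), n)
  membership[cbind(seq_len(n), primary)] <- TRUE
  if (overlap > 0 && module_count > 1) {
    extra <- which(stats::runif(n) < overlap)
    for (g in extra) {
      others <- setdiff(seq_len(module_count), primary[g])
      membership[g, others[sample.int(length(others), 1L)]] <- TRUE
    }
  }
  shared <- tcrossprod(membership) > 0  # genes sharing >= 1 module
  prob <- ifelse(shared, p_in, p_out)
  matrix(as.integer(stats::runif(n * n) < prob), n, n)
}

#' Synchronous network update
#'
#' Applies the difference equation `S_i(t+1) = sigma(sum_j w_ij S_j(t))` to
#' all live genes at once. Deleted genes (state 0) stay 0 and contribute
#' nothing (their rows and columns are zero anyway).
#'
#' @param state Integer vector over \{-1, 0, +1\}.
#' @param network [regulatory_network()] or bare weight matrix.
#' @return Updated state vector.
#' @examples
#' update_state(c(1, -1), matrix(c(0, 1, 1, 0), 2))  # swap map
#' @export
update_state <- function(state, network) {
  w <- as_weights(network)
  if (length(state) != nrow(w)) {
    stop("state length must match network dimension")
  }
  out <- sign_threshold(as.vector(w %*% state))
  out[state == 0] <- 0L
  out
}

#' Iterate to a stable fixed point
#'
#' Repeatedly applies [update_state()] until a state maps to itself, or
#' gives up after `max_iters` updates. Trajectories entering a cycle are
#' classed as non-converged (such networks are treated as non-viable).
#'
#' @param initial Starting state.
#' @param network [regulatory_network()] or weight matrix.
#' @param max_iters Update budget (default 100).
#' @return List with `converged` (logical), `equilibrium` (state or NULL)
#'   and `steps` (updates applied before the state stopped changing; 0 when
#'   `initial` is already a fixed point).
#' @export
find_fixed_point <- function(initial, network, max_iters = 100L) {
  if (max_iters < 1) stop("max_iters must be >= 1")
  w <- as_weights(network)
  if (length(initial) != nrow(w)) {
    stop("state length must match network dimension")
  }
  .cpp_fixed_point(as.integer(initial), w, as.integer(max_iters))
}

#' Simulation configuration for the network ensembles
#'
#' Bundles the model parameters with their standard values: networks of
#' `n_genes = 10`, full connectivity, perturbation sizes `k = 1..9`,
#' 1000 trials per `k`, a 100-update convergence budget.
#'
#' @param n_genes Network size N.
#' @param connectivity Fraction of nonzero weights, in (0, 1].
#' @param k_values Perturbation sizes to sweep.
#' @param trials_per_k Independent trials per `k`.
#' @param max_iters Update budget per trajectory.
#' @param max_rejection_attempts Weight-matrix draws allowed per
#'   (initial, target) pair before the pair itself is redrawn.
#' @param topology `"dense"` or `"modular"`.
#' @param module_count,overlap,p_in,p_out Modular-topology parameters.
#' @param deleted_state Value recorded for deleted genes when computing the
#'   Hamming statistic: `0` (default; matches the equilibrium coding) or
#'   `-1` (the off-state reading). Dynamics are identical either way —
#'   deleted genes are frozen and uncoupled — only the bookkeeping changes.
#' @param seed Master seed; per-(mode, k, trial) substreams are derived from
#'   it so sweeps are reproducible independently.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 10L, connectivity = 1,
                              k_values = 1:9, trials_per_k = 1000L,
                              max_iters = 100L,
                              max_rejection_attempts = 10000L,
                              topology = c("dense", "modular"),
                              module_count = 2L, overlap = 0,
                              p_in = 0.8, p_out = 0.05,
                              deleted_state = 0L, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_genes >= 1, trials_per_k >= 1, max_iters >= 1,
            all(k_values >= 1), all(k_values <= n_genes),
            deleted_state %in% c(0L, -1L))
  if (connectivity <= 0 || connectivity > 1) {
    stop("connectivity must lie in (0, 1]")
  }
  structure(list(n_genes = as.integer(n_genes), connectivity = connectivity,
                 k_values = as.integer(k_values),
                 trials_per_k = as.integer(trials_per_k),
                 max_iters = as.integer(max_iters),
                 max_rejection_attempts = as.integer(max_rejection_attempts),
                 topology = topology, module_count = as.integer(module_count),
                 overlap = overlap, p_in = p_in, p_out = p_out,
                 deleted_state = as.integer(deleted_state),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Rejection-sample a viable network set
#'
#' Draws an initial state `S(0)` and a target equilibrium `S_eq` (each gene
#' on/off with probability 1/2), then repeatedly draws weight matrices until
#' the trajectory from `S(0)` reaches the fixed point `S_eq` within
#' `max_iters` updates. Fails with a condition of class
#' `genelossr_no_viable_network` after `max_rejection_attempts` draws —
#' some (initial, target) pairs admit no viable weights at all (e.g. N = 1
#' with `S(0) = +1`, `S_eq = -1`).
#'
#' RNG protocol (dense topology): within an attempt, row `i` of the weight
#' matrix is drawn as `n` normals (followed by `n` mask uniforms when
#' `c < 1`); if row `i` violates the sign condition `sigma(w[i, ] %*%
#' S_eq) == S_eq[i]`, the attempt is rejected on the spot and later rows
#' draw nothing. Accepted matrices have exactly the masked-Gaussian
#' distribution conditioned on `S_eq` being a fixed point, and the
#' trajectory check from `S(0)` then decides acceptance.
#'
#' @param config A [simulation_config()].
#' @param initial,equilibrium Optional fixed states; drawn when NULL.
#' @return List of class `viable_network_set` with `initial`, `network`,
#'   `equilibrium`, `attempts_used`.
#' @export
sample_viable_network <- function(config = simulation_config(),
                                  initial = NULL, equilibrium = NULL) {
  n <- config$n_genes
  if (is.null(initial)) initial <- sample_state(n)
  if (is.null(equilibrium)) equilibrium <- sample_state(n)
  if (config$topology == "dense") {
    res <- .cpp_viable_search(as.integer(initial), as.integer(equilibrium),
                              config$connectivity, config$max_iters,
                              config$max_rejection_attempts)
    if (!res$found) {
      stop(no_viable_network_condition(config$max_rejection_attempts))
    }
    net <- regulatory_network(res$w, connectivity = config$connectivity)
    attempts <- res$attempts
  } else {
    attempts <- 0L
    net <- NULL
    while (attempts < config$max_rejection_attempts) {
      attempts <- attempts + 1L
      cand <- sample_network(n, config$connectivity, topology = "modular",
                             module_count = config$module_count,
                             overlap = config$overlap,
                             p_in = config$p_in, p_out = config$p_out)
      fp <- find_fixed_point(initial, cand, config$max_iters)
      if (fp$converged && identical(as.integer(fp$equilibrium),
                                    as.integer(equilibrium))) {
        net <- cand
        break
      }
    }
    if (is.null(net)) {
      stop(no_viable_network_condition(attempts))
    }
  }
  structure(list(initial = as.integer(initial), network = net,
                 equilibrium = as.integer(equilibrium),
                 attempts_used = attempts),
            class = "viable_network_set")
}

no_viable_network_condition <- function(attempts) {
  structure(class = c("genelossr_no_viable_network", "error", "condition"),
            list(message = sprintf(
                   "no viable network found after %d attempts", attempts),
                 call = NULL, attempts_used = attempts))
}

#' Delete genes from a viable network set
#'
#' The `k` deleted genes have their rows and columns of the weight matrix
#' zeroed and their entries of the initial state set to 0 (frozen). All
#' other weights and state entries are untouched.
#'
#' @param viable A `viable_network_set`.
#' @param k Number of genes to delete, `1 <= k <= N`.
#' @param indices Optional explicit gene indices; drawn uniformly when NULL.
#' @return List with `perturbed_initial`, `perturbed_network`,
#'   `deleted_indices`.
#' @export
delete_genes <- function(viable, k, indices = NULL) {
  n <- length(viable$initial)
  if (k < 1 || k > n) stop("k must lie in [1, N]")
  if (is.null(indices)) indices <- sample.int(n, k)
  indices <- as.integer(indices)
  if (length(indices) != k || anyDuplicated(indices)) {
    stop("indices must be k distinct genes")
  }
  w <- as_weights(viable$network)
  w[indices, ] <- 0
  w[, indices] <- 0
  s0 <- viable$initial
  s0[indices] <- 0L
  list(perturbed_initial = s0,
       perturbed_network = regulatory_network(
         w, connectivity = viable$network$connectivity,
         topology = viable$network$topology),
       deleted_indices = sort(indices))
}

#' Duplicate genes in a viable network set
#'
#' For each duplicated gene `i`, a copy `i'` is appended whose input row and
#' output column equal gene `i`'s, with `w[i', i'] = w[i', i] = w[i, i'] =
#' w[i, i]` so the copy is indistinguishable from the original; cross-terms
#' among multiple duplicates are copied from the corresponding originals.
#' The copy starts in its original's initial state.
#'
#' @inheritParams delete_genes
#' @return List with `perturbed_initial` (length N + k),
#'   `perturbed_network` ((N + k) x (N + k)), `duplicated_indices`.
#' @export
duplicate_genes <- function(viable, k, indices = NULL) {
  n <- length(viable$initial)
  if (k < 1 || k > n) stop("k must lie in [1, N]")
  if (is.null(indices)) indices <- sample.int(n, k)
  indices <- as.integer(indices)
  if (length(indices) != k || anyDuplicated(indices)) {
    stop("indices must be k distinct genes")
  }
  w <- as_weights(viable$network)
  src <- c(seq_len(n), indices)       # gene of origin for each extended index
  w2 <- w[src, src, drop = FALSE]
  dimnames(w2) <- NULL
  s0 <- viable$initial[src]
  list(perturbed_initial = as.integer(s0),
       perturbed_network = regulatory_network(
         w2, connectivity = viable$network$connectivity,
         topology = viable$network$topology),
       duplicated_indices = indices)
}

#' Hamming distance between expression states
#'
#' Number of positions at which two states differ; a 0-vs-(+/-)1 position
#' counts as a difference.
#'
#' @param a,b Equal-length state vectors.
#' @return Integer count.
#' @examples
#' hamming(c(1, 1, -1), c(1, -1, -1))
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) stop("states must have equal length")
  sum(a != b)
}

## Derive a per-(mode, k, trial) seed from the master seed with a small
## multiplicative-congruential mix (all arithmetic stays below 2^53).
derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (v in c(...)) h <- (h * 48271 + as.numeric(v) + 1) %% 2147483647
  as.integer(h)
}

run_one_trial <- function(config, mode, k) {
  n <- config$n_genes
  resamples <- 0L
  vb <- NULL
  repeat {
    vb <- tryCatch(sample_viable_network(config),
                   genelossr_no_viable_network = function(e) NULL)
    if (!is.null(vb)) break
    resamples <- resamples + 1L   # redraw (S0, Seq) and keep going
    if (resamples > 1000L) stop("viability resampling failed repeatedly")
  }
  if (mode == "deletion") {
    pert <- delete_genes(vb, k)
    fp <- find_fixed_point(pert$perturbed_initial, pert$perturbed_network,
                           config$max_iters)
    if (fp$converged) {
      eq_pert <- as.integer(fp$equilibrium)
      if (config$deleted_state == -1L) {
        eq_pert[pert$deleted_indices] <- -1L
      }
      dh <- hamming(eq_pert, vb$equilibrium)
      novel <- dh > k
    } else {
      dh <- NA_integer_; novel <- FALSE
    }
  } else {
    pert <- duplicate_genes(vb, k)
    fp <- find_fixed_point(pert$perturbed_initial, pert$perturbed_network,
                           config$max_iters)
    if (fp$converged) {
      dh <- hamming(as.integer(fp$equilibrium)[seq_len(n)], vb$equilibrium)
      novel <- dh > 0
    } else {
      dh <- NA_integer_; novel <- FALSE
    }
  }
  list(converged = fp$converged, dh = dh, novel = novel,
       attempts = vb$attempts_used, resamples = resamples)
}

#' Run a perturbation ensemble
#'
#' For each perturbation size `k`, runs `trials_per_k` independent trials:
#' sample a viable network set, delete (or duplicate) `k` random genes, and
#' iterate the perturbed network from the perturbed initial state. A
#' deletion trial yields a novel stable state when it converges and the
#' equilibrium differs from the original in more than `k` positions (the
#' `k` deleted positions differ by construction); a duplication trial when
#' it converges and the equilibrium restricted to the original N genes
#' differs at all. Non-converged trials stay in the denominator; their
#' count is reported so either normalization can be recovered.
#'
#' @param config A [simulation_config()].
#' @param mode `"deletion"` or `"duplication"`.
#' @param keep_trials Attach a per-trial data frame as attribute
#'   `"trials"`.
#' @return Data frame of class `loss_gain_ensemble`, one row per `k`, with
#'   columns `mode`, `k`, `c`, `trials`, `proportion_novel_stable`,
#'   `variance` (sample variance of the per-trial novelty indicator),
#'   `n_nonconverged`, `n_resampled`, `seed`.
#' @examples
#' cfg <- simulation_config(n_genes = 5, k_values = c(1, 2),
#'                          trials_per_k = 20, seed = 42)
#' run_ensemble(cfg, "deletion")
#' @export
run_ensemble <- function(config = simulation_config(),
                         mode = c("deletion", "duplication"),
                         keep_trials = FALSE) {
  mode <- match.arg(mode)
  mode_code <- if (mode == "deletion") 1L else 2L
  rows <- vector("list", length(config$k_values))
  trial_rows <- if (keep_trials) list() else NULL
  for (ki in seq_along(config$k_values)) {
    k <- config$k_values[ki]
    novel <- logical(config$trials_per_k)
    nonconv <- 0L
    resampled <- 0L
    dhs <- integer(config$trials_per_k)
    for (trial in seq_len(config$trials_per_k)) {
      set.seed(derive_seed(config$seed, mode_code, k, trial))
      tr <- run_one_trial(config, mode, k)
      novel[trial] <- tr$novel
      if (!tr$converged) nonconv <- nonconv + 1L
      resampled <- resampled + tr$resamples
      dhs[trial] <- if (is.na(tr$dh)) NA_integer_ else tr$dh
    }
    rows[[ki]] <- data.frame(
      mode = mode, k = k, c = config$connectivity,
      trials = config$trials_per_k,
      proportion_novel_stable = mean(novel),
      variance = stats::var(as.numeric(novel)),
      n_nonconverged = nonconv, n_resampled = resampled,
      seed = config$seed)
    if (keep_trials) {
      trial_rows[[ki]] <- data.frame(
        mode = mode, k = k, trial = seq_len(config$trials_per_k),
        converged = !is.na(dhs), d_h = dhs, novel = novel)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("loss_gain_ensemble", "data.frame")
  if (keep_trials) attr(out, "trials") <- do.call(rbind, trial_rows)
  out
}

#' Sweep network connectivity at fixed perturbation size
#'
#' Runs [run_ensemble()] at each connectivity value with `k` held fixed.
#'
#' @param config A [simulation_config()] (its `connectivity` is overridden).
#' @param c_values Connectivity values, each in (0, 1].
#' @param fixed_k Perturbation size used at every connectivity.
#' @param mode `"deletion"` or `"duplication"`.
#' @return `loss_gain_ensemble` data frame, one row per connectivity.
#' @export
connectivity_sweep <- function(config = simulation_config(),
                               c_values = seq(0.1, 0.9, by = 0.2),
                               fixed_k = 5L,
                               mode = c("deletion", "duplication")) {
  mode <- match.arg(mode)
  if (any(c_values <= 0 | c_values > 1)) {
    stop("all connectivity values must lie in (0, 1]")
  }
  rows <- lapply(c_values, function(cv) {
    cfg <- config
    cfg$connectivity <- cv
    cfg$k_values <- as.integer(fixed_k)
    run_ensemble(cfg, mode)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("loss_gain_ensemble", "data.frame")
  out
}

#' @export
print.loss_gain_ensemble <- function(x, ...) {
  cat("Perturbation ensemble (novel stable network states)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot novelty proportions against perturbation size
#'
#' Draws the proportion of trials yielding a novel stable state as a
#' function of `k` (or of connectivity for sweep results), one curve per
#' mode, with a shaded band of +/- one standard deviation of the novelty
#' indicator.
#'
#' @param x A `loss_gain_ensemble`.
#' @param xvar Column for the x axis, `"k"` or `"c"`.
#' @param ... Further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @method plot loss_gain_ensemble
#' @export
plot.loss_gain_ensemble <- function(x, xvar = c("k", "c"), ...) {
  xvar <- match.arg(xvar)
  modes <- unique(x$mode)
  cols <- c(deletion = "firebrick", duplication = "steelblue")
  plot(range(x[[xvar]]), c(0, max(x$proportion_novel_stable) * 1.1 + 0.02),
       type = "n", xlab = xvar, ylab = "proportion novel stable", ...)
  for (m in modes) {
    sub <- x[x$mode == m, ]
    sub <- sub[order(sub[[xvar]]), ]
    sd <- sqrt(sub$variance)
    polygon(c(sub[[xvar]], rev(sub[[xvar]])),
            c(pmax(0, sub$proportion_novel_stable - sd),
              rev(pmin(1, sub$proportion_novel_stable + sd))),
            col = grDevices::adjustcolor(cols[[m]], alpha.f = 0.2),
            border = NA)
    lines(sub[[xvar]], sub$proportion_novel_stable, col = cols[[m]],
          type = "b", pch = 16)
  }
  legend("topright", legend = modes, col = cols[modes], lty = 1, pch = 16,
         bty = "n")
  invisible(x)
}
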