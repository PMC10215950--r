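#' Leave-k-out resampling plan
#'
#' @param k_grid strictly increasing positive patient-removal counts;
#'   defaults to the study grid 1, 2, 3, 5, 10, 20, 30, 50.
#' @param replicates replicate count per k (default 100).
#' @param master_seed integer master seed; every replicate's seed is derived
#'   from it by a counter scheme (see [leave_k_out()]) so that the draw for
#'   replicate r at a given k does not depend on the ordering of `k_grid`.
#' @return object of class `resampling_plan`.
#' @export
resampling_plan <- function(k_grid = c(1L, 2L, 3L, 5L, 10L, 20L, 30L, 50L),
                            replicates = 100L, master_seed = 1L) {
  k_grid <- as.integer(k_grid)
  if (!length(k_grid)) stop("k_grid must not be empty")
  if (any(k_grid < 0)) stop("k values must be non-negative")
  if (is.unsorted(k_grid, strictly = TRUE))
    stop("k_grid must be strictly increasing")
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("replicates must be positive")
  structure(list(k_grid = k_grid, replicates = replicates,
                 master_seed = as_seed(master_seed)),
            class = "resampling_plan")
}

# per-(k, replicate) seed: distinct for all k <= 10^4, r <= 10^4 because
# 1009 and 9973 are coprime and the offsets cannot collide in that range
derive_seed <- function(master_seed, k, r) {
  as_seed(as.numeric(master_seed) + 1009 * as.numeric(k) + 9973 * as.numeric(r))
}

#' Retained index sets for leave-k-out replicates
#'
#' Each replicate removes a uniformly random k-subset of the `n` subjects
#' (without replacement), reproducibly from the derived per-replicate seed.
#' `k = 0` is allowed (every replicate retains the full index set), which is
#' useful as a self-agreement control.
#'
#' @param n dataset size.
#' @param k number of subjects to exclude, `0 <= k < n`.
#' @param replicates number of replicate draws.
#' @param master_seed integer seed.
#' @return list of `replicates` integer vectors of the retained indices
#'   (each of length `n - k`, in increasing order).
#' @export
leave_k_out <- function(n, k, replicates = 100L, master_seed = 1L) {
  if (k < 0 || k >= n) stop("k must satisfy 0 <= k < n")
  lapply(seq_len(replicates), function(r) {
    if (k == 0) return(seq_len(n))
    set.seed(derive_seed(master_seed, k, r))
    sort(setdiff(seq_len(n), sample.int(n, k)))
  })
}

#' Learner settings for the resampling pillars
#'
#' @param alpha significance level of the conditional independence tests
#'   (default 0.005).
#' @param test `"g2"` or `"symmetric"`.
#' @param max_cond largest conditioning-set size.
#' @param directed_absent_cost SHD cost of a directed-vs-absent pair.
#' @return object of class `learner_settings`.
#' @export
learner_settings <- function(alpha = 0.005, test = "g2", max_cond = 3L,
                             directed_absent_cost = 2) {
  structure(list(alpha = alpha, test = test, max_cond = max_cond,
                 directed_absent_cost = directed_absent_cost),
            class = "learner_settings")
}

learn_with <- function(ds, settings) {
  learn_cpdag(ds, alpha = settings$alpha, test = settings$test,
              max_cond = settings$max_cond)
}

# shared replicate loop: returns rows from fn(k, r, retained-seed indices)
replicate_loop <- function(plan, n_list, fn) {
  rows <- list()
  failed <- list()
  for (k in plan$k_grid) {
    n_fail <- 0L
    for (r in seq_len(plan$replicates)) {
      idx <- lapply(n_list, function(n) {
        if (k >= n) stop("k = ", k, " is not smaller than dataset size ", n)
        if (k == 0) return(seq_len(n))
        set.seed(derive_seed(plan$master_seed, k, r))
        sort(setdiff(seq_len(n), sample.int(n, k)))
      })
      # second dataset (pillar II) draws an independent exclusion set
      if (length(n_list) == 2) {
        set.seed(derive_seed(plan$master_seed + 499979, k, r))
        n2 <- n_list[[2]]
        idx[[2]] <- if (k == 0) seq_len(n2)
                    else sort(setdiff(seq_len(n2), sample.int(n2, k)))
      }
      res <- tryCatch(fn(k, r, idx), error = function(e) e)
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1L
        failed[[length(failed) + 1L]] <-
          data.frame(k = k, replicate = r, message = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- res
    }
    if (n_fail > 0.1 * plan$replicates)
      stop("more than 10% of replicates failed at k = ", k)
  }
  list(long = do.call(rbind, rows),
       failed = if (length(failed)) do.call(rbind, failed) else NULL)
}

#' Pillar I: stability of one learned structure under leave-k-out
#'
#' Learns the reference CPDAG on the full dataset, then for every
#' (k, replicate) re-learns the structure on the retained subjects and
#' compares it to the reference with [edge_overlap()]. Per-k summaries are
#' means over replicates of the unrounded per-replicate values.
#'
#' @param ds a complete-case `genotype_dataset` (typically one part of the
#'   outcome split, without the outcome column).
#' @param plan a `resampling_plan`.
#' @param settings a `learner_settings`.
#' @return object of class `pillar_one`: list with `reference` (the full-
#'   data CPDAG), `long` (per-replicate data.frame), `summary` (per-k mean
#'   table), `failed` (failed-replicate log or `NULL`).
#' @export
run_pillar_one <- function(ds, plan = resampling_plan(),
                           settings = learner_settings()) {
  ref <- learn_with(ds, settings)
  n <- n_subjects(ds)
  res <- replicate_loop(plan, list(n), function(k, r, idx) {
    g <- learn_with(ds[idx[[1]]], settings)
    ov <- edge_overlap(ref, g, settings$directed_absent_cost)
    data.frame(k = k, replicate = r,
               common_undirected = ov$common_undirected,
               common_directed = ov$common_directed,
               directed_to_undirected = ov$directed_to_undirected,
               directed_reversed = ov$directed_reversed,
               directed_vanished = ov$directed_vanished,
               shd = ov$shd)
  })
  structure(list(reference = ref, long = res$long,
                 summary = pillar_one_summary(res$long, ref),
                 failed = res$failed, plan = plan, settings = settings),
            class = "pillar_one")
}

pillar_one_summary <- function(long, ref) {
  ec <- edge_counts(ref)
  n_nodes <- length(ref$nodes)
  agg <- stats::aggregate(
    long[c("common_undirected", "common_directed", "directed_to_undirected",
           "directed_reversed", "directed_vanished", "shd")],
    by = list(k = long$k), FUN = mean)
  data.frame(
    k = agg$k,
    mean_common_undirected = agg$common_undirected,
    pct_common_undirected = pct_of(agg$common_undirected, ec[["undirected"]]),
    mean_common_directed = agg$common_directed,
    pct_common_directed = pct_of(agg$common_directed, ec[["directed"]]),
    mean_directed_to_undirected = agg$directed_to_undirected,
    pct_directed_to_undirected = pct_of(agg$directed_to_undirected,
                                        ec[["directed"]]),
    mean_directed_reversed = agg$directed_reversed,
    pct_directed_reversed = pct_of(agg$directed_reversed, ec[["directed"]]),
    mean_shd = agg$shd,
    relative_shd_pct = relative_shd(agg$shd, n_nodes))
}

#' Pillar II: stability of the similarity between two learned structures
#'
#' Compares the CPDAGs learned on two datasets (e.g. the zero-outcome and
#' positive-outcome subpopulations): first the unperturbed baseline (common
#' undirected/directed counts and SHD), then per (k, replicate) after
#' independently excluding k subjects from each dataset.
#'
#' @param ds0,ds1 complete-case `genotype_dataset`s over the same variables.
#' @param plan a `resampling_plan`.
#' @param settings a `learner_settings`.
#' @return object of class `pillar_two`: `reference0`, `reference1`,
#'   `baseline` (counts/SHD between the two full-data structures), `long`,
#'   `summary`, `failed`.
#' @export
run_pillar_two <- function(ds0, ds1, plan = resampling_plan(),
                           settings = learner_settings()) {
  if (!identical(ds0$variables, ds1$variables))
    stop("the two datasets must share the same variables")
  g0 <- learn_with(ds0, settings)
  g1 <- learn_with(ds1, settings)
  base_ov <- edge_overlap(g0, g1, settings$directed_absent_cost)
  baseline <- list(common_undirected = base_ov$common_undirected,
                   common_directed = base_ov$common_directed,
                   shd = base_ov$shd)
  res <- replicate_loop(plan, list(n_subjects(ds0), n_subjects(ds1)),
                        function(k, r, idx) {
    h0 <- learn_with(ds0[idx[[1]]], settings)
    h1 <- learn_with(ds1[idx[[2]]], settings)
    ov <- edge_overlap(h0, h1, settings$directed_absent_cost)
    data.frame(k = k, replicate = r,
               common_undirected = ov$common_undirected,
               common_directed = ov$common_directed,
               shd = ov$shd)
  })
  long <- res$long
  agg <- stats::aggregate(long[c("common_undirected", "common_directed", "shd")],
                          by = list(k = long$k), FUN = mean)
  summary <- data.frame(
    k = agg$k,
    mean_common_undirected = agg$common_undirected,
    ratio_common_undirected = if (baseline$common_undirected > 0)
      round_half_up(agg$common_undirected / baseline$common_undirected)
      else NA_real_,
    mean_common_directed = agg$common_directed,
    ratio_common_directed = if (baseline$common_directed > 0)
      round_half_up(agg$common_directed / baseline$common_directed)
      else NA_real_,
    mean_shd = agg$shd,
    relative_shd_pct = relative_shd(agg$shd, length(g0$nodes)))
  structure(list(reference0 = g0, reference1 = g1, baseline = baseline,
                 long = long, summary = summary, failed = res$failed,
                 plan = plan, settings = settings),
            class = "pillar_two")
}

#' Pillar III: stability of the outcome's Markov blanket
#'
#' Determines the reference Markov blanket of `target` on the full dataset
#' (outcome included as a categorical variable), then re-determines it per
#' (k, replicate) on the retained subjects, tallying per-variable inclusion
#' percentages, the distribution of how many reference-blanket variables
#' are recovered, and the mean number of extra variables.
#'
#' @param ds a complete-case `genotype_dataset` retaining the (discretized)
#'   outcome column.
#' @param target the outcome variable name (defaults to the dataset's
#'   outcome column).
#' @param plan a `resampling_plan`.
#' @param settings a `learner_settings`.
#' @return object of class `pillar_three`: `reference` (CPDAG),
#'   `reference_mb`, `long` (per-replicate blanket memberships), `summary`
#'   (per-k inclusion/exact-count/extras table), `inclusion` (all-variable
#'   inclusion percentage matrix, variables x k), `failed`.
#' @export
run_pillar_three <- function(ds, target = ds$outcome_name,
                             plan = resampling_plan(),
                             settings = learner_settings()) {
  if (is.null(target)) stop("a target variable is required")
  if (!target %in% ds$variables) stop("target '", target, "' not in dataset")
  ref <- learn_with(ds, settings)
  ref_mb <- markov_blanket(ref, target)
  others <- setdiff(ds$variables, target)
  res <- replicate_loop(plan, list(n_subjects(ds)), function(k, r, idx) {
    g <- learn_with(ds[idx[[1]]], settings)
    mb <- markov_blanket(g, target)
    row <- data.frame(k = k, replicate = r,
                      n_initial_in_mb = length(intersect(mb, ref_mb)),
                      n_extra_in_mb = length(setdiff(mb, ref_mb)),
                      mb = paste(mb, collapse = ";"))
    member <- matrix(as.integer(others %in% mb), nrow = 1,
                     dimnames = list(NULL, others))
    cbind(row, as.data.frame(member, check.names = FALSE))
  })
  long <- res$long
  ks <- sort(unique(long$k))
  inclusion <- sapply(ks, function(k) {
    sub <- long[long$k == k, others, drop = FALSE]
    round_half_up(100 * colMeans(sub))
  })
  inclusion <- matrix(inclusion, nrow = length(others),
                      dimnames = list(others, ks))
  n_init <- length(ref_mb)
  exact <- sapply(ks, function(k) {
    x <- long$n_initial_in_mb[long$k == k]
    vapply(0:n_init, function(m) round_half_up(100 * mean(x == m)), numeric(1))
  })
  exact <- matrix(exact, nrow = n_init + 1,
                  dimnames = list(paste0("exactly_", 0:n_init), ks))
  extras <- vapply(ks, function(k)
    mean(long$n_extra_in_mb[long$k == k]), numeric(1))
  summary <- list(k = ks,
                  inclusion_initial = inclusion[ref_mb, , drop = FALSE],
                  exact_counts_pct = exact,
                  mean_extra = stats::setNames(extras, ks))
  structure(list(reference = ref, reference_mb = ref_mb, long = long,
                 summary = summary, inclusion = inclusion,
                 failed = res$failed, plan = plan, settings = settings,
                 target = target),
            class = "pillar_three")
}
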