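#' Wide presentation table for a pillar-I result
#'
#' One row per metric (mean counts, mean percentages of the reference
#' totals, mean SHD and relative SHD), one column per k; percentages and
#' means rounded half-up to two decimals.
#'
#' @param p1 a `pillar_one` object.
#' @return data.frame with a `metric` column and one column per k.
#' @export
format_pillar_one <- function(p1) {
  s <- p1$summary
  rows <- rbind(
    "mean number of common undirected edges" = s$mean_common_undirected,
    "mean percentage of common undirected edges (%)" = s$pct_common_undirected,
    "mean number of common directed edges" = s$mean_common_directed,
    "mean percentage of common directed edges (%)" = s$pct_common_directed,
    "mean number of directed edges turned undirected" = s$mean_directed_to_undirected,
    "mean percentage of directed edges turned undirected (%)" = s$pct_directed_to_undirected,
    "mean number of directed edges that changed direction" = s$mean_directed_reversed,
    "mean percentage of directed edges that changed direction (%)" = s$pct_directed_reversed,
    "mean structural Hamming distance" = s$mean_shd,
    "mean relative structural Hamming distance (%)" = s$relative_shd_pct)
  out <- data.frame(metric = rownames(rows),
                    round_half_up(rows), check.names = FALSE,
                    row.names = NULL)
  names(out)[-1] <- paste0("k=", s$k)
  out
}

#' Wide presentation table for a pillar-II result
#'
#' @param p2 a `pillar_two` object.
#' @return data.frame with a `metric` column and one column per k.
#' @export
format_pillar_two <- function(p2) {
  s <- p2$summary
  rows <- rbind(
    "mean number of common undirected edges" = s$mean_common_undirected,
    "mean ratio of common undirected edges to baseline" = s$ratio_common_undirected,
    "mean number of common directed edges" = s$mean_common_directed,
    "mean ratio of common directed edges to baseline" = s$ratio_common_directed,
    "mean structural Hamming distance" = s$mean_shd,
    "mean relative structural Hamming distance (%)" = s$relative_shd_pct)
  out <- data.frame(metric = rownames(rows),
                    round_half_up(rows), check.names = FALSE,
                    row.names = NULL)
  names(out)[-1] <- paste0("k=", s$k)
  out
}

#' Wide presentation table for a pillar-III result
#'
#' Per-variable inclusion percentages of the reference-blanket members, the
#' exactly-m-of-|MB| distribution (whose columns sum to 100 per k), and the
#' mean number of extra variables.
#'
#' @param p3 a `pillar_three` object.
#' @return data.frame with a `metric` column and one column per k.
#' @export
format_pillar_three <- function(p3) {
  s <- p3$summary
  n_init <- length(p3$reference_mb)
  rows <- rbind(
    s$inclusion_initial,
    s$exact_counts_pct,
    "mean number of extra variables in the blanket" =
      round_half_up(s$mean_extra))
  labels <- c(sprintf("%s inclusion (%%)", p3$reference_mb),
              sprintf("exactly %d of %d included (%%)", 0:n_init, n_init),
              "mean number of extra variables in the blanket")
  out <- data.frame(metric = labels, rows, check.names = FALSE,
                    row.names = NULL)
  names(out)[-1] <- paste0("k=", s$k)
  out
}

#' Write pillar results, long tables and a manifest to a directory
#'
#' Writes, for every supplied pillar object, the wide per-k presentation
#' table and the tidy per-replicate long table as CSV, the learned reference
#' structures in the edge-list format, and a YAML manifest echoing the
#' configuration, seeds and package version so a run can be reproduced
#' exactly. File contents contain no timestamps: re-running with the same
#' seed reproduces them byte for byte.
#'
#' @param dir output directory (created; must not exist unless
#'   `force = TRUE`).
#' @param pillar1,pillar2,pillar3 optional pillar result objects.
#' @param config optional configuration list echoed into the manifest.
#' @param force overwrite an existing directory.
#' @return `dir`, invisibly.
#' @export
summarize_tables <- function(dir, pillar1 = NULL, pillar2 = NULL,
                             pillar3 = NULL, config = NULL, force = FALSE) {
  if (is.null(pillar1) && is.null(pillar2) && is.null(pillar3))
    stop("at least one pillar result is required")
  if (dir.exists(dir) && !force)
    stop("output directory exists (use force = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  manifest <- list(package = "causalstab",
                   version = as.character(utils::packageVersion("causalstab")),
                   config = config)
  if (!is.null(pillar1)) {
    wcsv(format_pillar_one(pillar1), "pillar1_wide.csv")
    wcsv(pillar1$long, "pillar1_long.csv")
    write_graph(pillar1$reference, file.path(dir, "pillar1_reference.graph"))
    manifest$pillar1 <- plan_echo(pillar1)
  }
  if (!is.null(pillar2)) {
    wcsv(format_pillar_two(pillar2), "pillar2_wide.csv")
    wcsv(pillar2$long, "pillar2_long.csv")
    write_graph(pillar2$reference0, file.path(dir, "pillar2_reference0.graph"))
    write_graph(pillar2$reference1, file.path(dir, "pillar2_reference1.graph"))
    manifest$pillar2 <- c(plan_echo(pillar2),
                          list(baseline = pillar2$baseline))
  }
  if (!is.null(pillar3)) {
    wcsv(format_pillar_three(pillar3), "pillar3_wide.csv")
    wcsv(pillar3$long, "pillar3_long.csv")
    write_graph(pillar3$reference, file.path(dir, "pillar3_reference.graph"))
    manifest$pillar3 <- c(plan_echo(pillar3),
                          list(reference_mb = pillar3$reference_mb))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

plan_echo <- function(p) {
  list(k_grid = p$plan$k_grid, replicates = p$plan$replicates,
       master_seed = p$plan$master_seed,
       alpha = p$settings$alpha, test = p$settings$test,
       max_cond = p$settings$max_cond)
}
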