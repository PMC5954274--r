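#' Pipeline configuration
#'
#' One object holding every stage parameter of the resolution-sweep
#' analysis.  Input is either a simulation configuration (default) or three
#' pairwise block-table TSV paths plus the pivot genome name.
#'
#' @param sim a [sim_config()] used when no tables are supplied.
#' @param tables optional named list with elements `ab`, `bc`, `ca`: paths
#'   to pairwise block-table TSVs (or [block_table] objects); `ab` and `bc`
#'   must place the pivot.
#' @param pivot pivot genome name (default: first simulated genome name).
#' @param schedule a [resolution_schedule()].
#' @param size_method block-size summary for the level filter
#'   (`"min"`/`"mean"`/`"max"`).
#' @param filter_scaffolds apply the informative-scaffold filter before the
#'   sweep (default `TRUE`).
#' @param polarity run [resolve_polarity()] on indeterminate merged blocks
#'   at every level, with the DCJ median score as objective (default
#'   `TRUE`; this is the costly stage).
#' @param enumerate enumerate all co-optimal medians per level (default
#'   `TRUE`).
#' @param cap enumeration cap (default 50000).
#' @param scenarios compute translocation/reversal scenario counts under
#'   both priority modes (default `TRUE`).
#' @param estimator list with `variant` and `factor2_omitted` for
#'   [estimate_t()] (defaults `eq7`, `TRUE`).
#' @return list of class `granulome_config`.
#' @export
granulome_config <- function(sim = sim_config(), tables = NULL, pivot = NULL,
                             schedule = resolution_schedule(),
                             size_method = "min", filter_scaffolds = TRUE,
                             polarity = TRUE, enumerate = TRUE, cap = 50000L,
                             scenarios = TRUE,
                             estimator = list(variant = "eq7",
                                              factor2_omitted = TRUE)) {
  structure(list(sim = sim, tables = tables,
                 pivot = pivot %||% sim$genome_names[1],
                 schedule = schedule, size_method = size_method,
                 filter_scaffolds = isTRUE(filter_scaffolds),
                 polarity = isTRUE(polarity), enumerate = isTRUE(enumerate),
                 cap = as.integer(cap), scenarios = isTRUE(scenarios),
                 estimator = estimator),
            class = "granulome_config")
}

#' Run the full resolution-sweep analysis
#'
#' Simulates (or ingests) three pairwise synteny-block tables, builds the
#' three-way blocks, filters uninformative pivot scaffolds, sweeps the
#' resolution levels, and at every level computes the exact DCJ median, its
#' distance profile, breakpoint distances, normalized totals, breakpoint
#' reuse per genome pair, scenario operation counts under both priority
#' modes, and the conserved-synteny translocation estimate per genome.
#'
#' @param config a [granulome_config()].
#' @param out_dir optional directory; when given, the three-way table, the
#'   per-level genomes and median representatives (GRIMM text), and the
#'   summary TSV are written there.
#' @return object of class `granulome_run`: list with `summary` (one row
#'   per level), `sweep` (the [sweep_resolution()] result), `medians`
#'   (per-level [median_result][dcj_median]), `three_way` (the filtered
#'   table), `truth` (when simulated) and `config`.
#' @export
run_granulome <- function(config = granulome_config(), out_dir = NULL) {
  truth <- NULL
  if (is.null(config$tables)) {
    simres <- simulate_dataset(config$sim)
    tabs <- simres$tables
    truth <- simres$truth
  } else {
    tabs <- lapply(config$tables, function(x)
      if (is.character(x)) read_block_table(x) else x)
  }
  pivot <- config$pivot
  tw <- build_three_way(tabs$ab, tabs$bc, tabs$ca, pivot_genome = pivot)
  if (config$filter_scaffolds)
    tw <- filter_informative_scaffolds(tw, pivot)
  gn <- genomes_of_table(tw)
  sw <- sweep_resolution(tw, config$schedule, config$size_method)
  med_list <- list()
  rows <- list()
  for (k in seq_len(nrow(sw$report))) {
    L <- sw$report$level[k]
    lev <- sw$levels[[as.character(L)]]
    genomes <- lev$genomes
    if (config$polarity && nrow(lev$indeterminate)) {
      rp <- resolve_polarity(genomes, lev$indeterminate)
      genomes <- rp$genomes
    }
    med <- dcj_median(genomes[[1]], genomes[[2]], genomes[[3]],
                      enumerate_all = config$enumerate, cap = config$cap)
    med_list[[as.character(L)]] <- med
    rep_m <- med$medians[[1]]
    n_blk <- nrow(lev$table)
    row <- cbind(sw$report[k, , drop = FALSE],
                 data.frame(median_total = med$total_score,
                            n_medians = med$n_medians,
                            truncated = med$truncated,
                            norm_total = normalized_total(med$total_score,
                                                          max(1L, n_blk))))
    bp_tot <- 0
    for (g in gn) {
      dg <- med$distances[[g]]
      bg <- breakpoint_distance(rep_m, genomes[[g]])
      bp_tot <- bp_tot + bg
      row[[paste0("d_m_", g)]] <- dg
      row[[paste0("bp_m_", g)]] <- bg
    }
    row$bp_total <- bp_tot
    pairs <- utils::combn(gn, 2, simplify = FALSE)
    for (pr in pairs) {
      r <- tryCatch(reuse_rate(genomes[[pr[1]]], genomes[[pr[2]]]),
                    error = function(e) NA_real_)
      row[[paste0("r_", pr[1], "_", pr[2])]] <- r
    }
    if (config$scenarios) {
      for (g in gn) {
        sc_t <- sort_scenario(rep_m, genomes[[g]], "translocations")
        sc_r <- sort_scenario(rep_m, genomes[[g]], "reversals")
        ct <- scenario_counts(sc_t)
        cr <- scenario_counts(sc_r)
        row[[paste0("trans_max_", g)]] <- ct[["translocation"]]
        row[[paste0("trans_min_", g)]] <- cr[["translocation"]]
        row[[paste0("rev_max_", g)]] <- cr[["reversal"]]
        row[[paste0("rev_min_", g)]] <- ct[["reversal"]]
        row[[paste0("fus_fis_", g)]] <- ct[["fusion"]] + ct[["fission"]]
      }
    }
    for (g in gn) {
      lens <- lev$table[[paste0(g, "_genes")]]
      names(lens) <- lev$table$block_id
      t_hat <- tryCatch(
        estimate_t(conserved_syntenies(rep_m, genomes[[g]], lens),
                   variant = config$estimator$variant,
                   factor2_omitted = config$estimator$factor2_omitted)$t_hat,
        error = function(e) NA_real_)
      row[[paste0("t_hat_", g)]] <- t_hat
    }
    rows[[k]] <- row
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  res <- structure(list(summary = summary, sweep = sw, medians = med_list,
                        three_way = tw, truth = truth, config = config,
                        genome_names = gn),
                   class = "granulome_run")
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

#' @export
print.granulome_run <- function(x, ...) {
  cat("<granulome_run> ", nrow(x$summary), " resolution level(s), genomes: ",
      paste(x$genome_names, collapse = ", "), "\n", sep = "")
  cols <- intersect(c("level", "blocks_after_mergers", "genes_remaining",
                      "median_total", "n_medians", "norm_total"),
                    names(x$summary))
  print(x$summary[, cols], row.names = FALSE)
  invisible(x)
}

write_run_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_block_table(res$three_way, file.path(out_dir, "three_way.tsv"))
  utils::write.table(res$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (L in names(res$sweep$levels)) {
    lev_dir <- file.path(out_dir, paste0("level_", L))
    dir.create(lev_dir, showWarnings = FALSE)
    lev <- res$sweep$levels[[L]]
    write_block_table(lev$table, file.path(lev_dir, "blocks.tsv"))
    for (g in names(lev$genomes))
      write_genome(lev$genomes[[g]], file.path(lev_dir, paste0(g, ".grimm")))
    med <- res$medians[[L]]
    if (!is.null(med))
      write_genome(med$medians[[1]], file.path(lev_dir, "median.grimm"))
  }
  invisible(out_dir)
}

#' Trend of breakpoint reuse across resolution levels
#'
#' Ordinary least squares of the pooled per-pair reuse statistic `r`
#' against the level `L`; the positive slope quantifies the descent into
#' randomness as resolution decreases.
#'
#' @param summary the `summary` data.frame of a [run_granulome()] result
#'   (or the result itself).
#' @return list with `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
reuse_trend <- function(summary) {
  if (inherits(summary, "granulome_run")) summary <- summary$summary
  rcols <- grep("^r_", names(summary), value = TRUE)
  if (!length(rcols)) stop("summary has no reuse (r_) columns")
  df <- data.frame(
    L = rep(summary$level, times = length(rcols)),
    r = unlist(summary[rcols], use.names = FALSE))
  df <- df[is.finite(df$r), ]
  if (nrow(df) < 3L) stop("need at least 3 defined reuse values")
  fit <- stats::lm(r ~ L, data = df)
  s <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared, n_points = nrow(df))
}
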