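# One-call pipeline: demultiplex -> trim -> dereplicate -> cluster ->
# filter -> assign -> diet metrics -> community stats, with stage-count
# bookkeeping and a round-trippable configuration.

#' Pipeline configuration
#'
#' Collects every tunable with its default. The configuration round-trips
#' losslessly through [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param max_mid_mismatch MID tag mismatches tolerated (default 0).
#' @param primer_fwd,primer_rev amplification primers.
#' @param primer_max_mismatch substitutions tolerated per primer site.
#' @param identity_threshold clustering identity (default 0.98).
#' @param min_length,min_reads cluster filters (defaults 40 bp, 4 reads).
#' @param min_identity,min_aligned assignment thresholds (defaults 0.95,
#'   40).
#' @param match,mismatch,gap_open,gap_extend alignment scoring.
#' @param nmds_k,nmds_starts,nmds_max_iter,nmds_tol ordination settings.
#' @param n_perm ANOSIM permutations (default 999).
#' @param seed global seed for the stochastic stages.
#' @return list of class `trnl_config`.
#' @export
pipeline_config <- function(max_mid_mismatch = 0,
                            primer_fwd = trnl_primers()[["g"]],
                            primer_rev = trnl_primers()[["h"]],
                            primer_max_mismatch = 0,
                            identity_threshold = 0.98,
                            min_length = 40, min_reads = 4,
                            min_identity = 0.95, min_aligned = 40,
                            match = 1, mismatch = -1,
                            gap_open = 2, gap_extend = 1,
                            nmds_k = 2, nmds_starts = 20,
                            nmds_max_iter = 200, nmds_tol = 1e-6,
                            n_perm = 999, seed = 1) {
  structure(as.list(environment()), class = "trnl_config")
}

#' Write / read a pipeline configuration
#'
#' YAML on disk; numeric and character scalars survive the round trip
#' unchanged.
#'
#' @param cfg configuration from [pipeline_config()].
#' @param path file path.
#' @return `path` (writer) / the configuration (reader).
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Run the full diet-metabarcoding pipeline
#'
#' Executes every stage on tagged reads plus a reference database and
#' returns all tables, statistics and stage-count logs. Identical inputs
#' and configuration give identical outputs.
#'
#' @param reads tibble of raw tagged reads (`read_id`, `seq`).
#' @param mids MID map tibble.
#' @param groups haplotype groups ([build_haplotype_groups()] or
#'   `build_reference_db()$groups`).
#' @param taxonomy taxonomy tibble.
#' @param meta optional sample metadata (enables monthly and island
#'   analyses).
#' @param cfg configuration from [pipeline_config()].
#' @return list of class `trnl_run` with elements `assignments`, `diet`
#'   (diet matrix), `summary` (diet summary table), `richness`, `clusters`,
#'   `rejected`, `tally`, `log` (stage bookkeeping tibble), and -- when
#'   `meta` is given -- `monthly`, `chao_d`, `chao_d_binary`, `nmds`,
#'   `anosim`, `anosim_binary`, `chisq`.
#' @export
run_pipeline <- function(reads, mids, groups, taxonomy, meta = NULL,
                         cfg = pipeline_config()) {
  params <- align_params(cfg$match, cfg$mismatch, cfg$gap_open, cfg$gap_extend)
  demux <- demultiplex(reads, mids, cfg$max_mid_mismatch)
  n_unassigned_mid <- sum(is.na(demux$sample_id))
  by_sample <- split(
    demux[!is.na(demux$sample_id), c("read_id", "seq", "sample_id")],
    demux$sample_id[!is.na(demux$sample_id)]
  )
  if (!length(by_sample)) {
    warn("no reads demultiplexed: outputs are empty")
  }

  processed <- purrr::imap(by_sample, function(rd, sid) {
    res <- process_sample_reads(rd,
      primer_fwd = cfg$primer_fwd, primer_rev = cfg$primer_rev,
      max_mismatch = cfg$primer_max_mismatch,
      identity_threshold = cfg$identity_threshold,
      min_length = cfg$min_length, min_reads = cfg$min_reads,
      params = params
    )
    res$clusters$sample_id <- rep(sid, nrow(res$clusters))
    res
  })
  clusters <- bind_rows(purrr::map(processed, "clusters"))
  rejected <- bind_rows(purrr::map(processed, function(x) x$rejected))
  retained <- if (nrow(clusters)) clusters[clusters$retained, ] else clusters

  assignments <- assign_clusters(retained, groups, taxonomy,
    min_identity = cfg$min_identity, min_aligned = cfg$min_aligned,
    params = params
  )
  tally <- if (nrow(assignments)) assignment_tally(assignments) else
    tibble(total_reads = 0, assigned_reads = 0, unassigned_reads = 0)
  diet <- diet_matrix(assignments)

  log <- tibble(
    stage = c("input", "demultiplexed", "mid_unassigned", "primer_rejected",
              "clustered", "filter_retained", "assigned", "hit_unassigned"),
    reads = c(
      nrow(reads), nrow(reads) - n_unassigned_mid, n_unassigned_mid,
      nrow(rejected),
      if (nrow(clusters)) sum(clusters$read_count) else 0,
      if (nrow(retained)) sum(retained$read_count) else 0,
      tally$assigned_reads, tally$unassigned_reads
    )
  )

  out <- list(
    assignments = assignments, diet = diet,
    summary = if (nrow(diet) && ncol(diet) > 1)
      diet_summary_table(diet, groups, taxonomy) else tibble(),
    richness = if (nrow(diet)) taxa_per_sample(diet) else tibble(),
    clusters = clusters, rejected = rejected, tally = tally, log = log,
    cfg = cfg
  )

  if (!is.null(meta) && nrow(diet) > 2 && ncol(diet) > 2) {
    out$monthly <- monthly_relative_frequency(diet, meta)
    out$chao_d <- chao_distance(diet)
    out$chao_d_binary <- chao_distance(diet, binary = TRUE)
    grp <- setNames(meta$island, meta$sample_id)[diet$sample_id]
    if (length(unique(grp)) > 1) {
      out$nmds <- nmds(out$chao_d_binary,
        k = cfg$nmds_k, n_starts = cfg$nmds_starts,
        max_iter = cfg$nmds_max_iter, tol = cfg$nmds_tol, seed = cfg$seed
      )
      out$anosim <- anosim_test(out$chao_d, grp, n_perm = cfg$n_perm, seed = cfg$seed)
      out$anosim_binary <- anosim_test(out$chao_d_binary, grp,
        n_perm = cfg$n_perm, seed = cfg$seed
      )
      pooled <- diet |>
        mutate(island = grp) |>
        tidyr::pivot_longer(-c("sample_id", "island"),
          names_to = "label", values_to = "reads"
        ) |>
        group_by(.data$island, .data$label) |>
        summarise(reads = sum(.data$reads), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "island", values_from = "reads")
      tab <- as.matrix(pooled[, -1])
      rownames(tab) <- pooled$label
      out$chisq <- tryCatch(pearson_chisq(tab), error = function(e) NULL)
    }
  }
  structure(out, class = "trnl_run")
}

#' @export
print.trnl_run <- function(x, ...) {
  cat("trnL P6-loop diet pipeline run\n")
  print(x$log)
  if (!is.null(x$anosim_binary)) {
    cat(sprintf("island ANOSIM (presence/absence): R = %.4f, p = %.4g\n",
                x$anosim_binary$R, x$anosim_binary$p.value))
  }
  invisible(x)
}

#' Write the result bundle of a run to a directory
#'
#' Tab-separated tables plus a small JSON of the headline statistics.
#'
#' @param run result of [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(run$assignments[, c("sample_id", "cluster_id", "label",
                                     "rank", "read_count", "best_identity")],
                 file.path(dir, "assignments.tsv"))
  write_tsv_file(run$diet, file.path(dir, "diet_matrix.tsv"))
  if (nrow(run$summary)) write_tsv_file(run$summary, file.path(dir, "diet_summary.tsv"))
  write_tsv_file(run$log, file.path(dir, "stage_log.tsv"))
  stats <- list(
    total_reads = run$tally$total_reads,
    assigned_reads = run$tally$assigned_reads,
    unassigned_reads = run$tally$unassigned_reads
  )
  if (!is.null(run$anosim_binary)) {
    stats$anosim_presence <- list(R = run$anosim_binary$R, p = run$anosim_binary$p.value)
    stats$anosim_reads <- list(R = run$anosim$R, p = run$anosim$p.value)
    stats$nmds_stress <- run$nmds$stress
  }
  if (!is.null(run$chisq)) {
    stats$chisq <- list(X2 = run$chisq$statistic, df = run$chisq$df,
                        p = run$chisq$p.value)
  }
  writeLines(yaml::as.yaml(stats), file.path(dir, "stats.yaml"))
  invisible(dir)
}
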