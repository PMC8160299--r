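#' Assemble a run report from stage outputs
#'
#' Produces a single markdown document summarizing whichever stage outputs
#' are supplied — the core-set table with per-dataset tiers, regional
#' differential calls, and single-cell cluster contrasts — the package's
#' analogue of a tabular receptor-regulation summary figure. TSV appendices
#' are written next to the report. Report generation is pure: re-running on
#' the same inputs yields byte-identical files (no timestamps).
#'
#' @param consensus Optional `consensus_result`.
#' @param region_diff Optional `region_diff` data.frame.
#' @param sc_contrast Optional `cluster_contrast` data.frame.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the path of the markdown report.
#' @export
assemble_report <- function(consensus = NULL, region_diff = NULL,
                            sc_contrast = NULL, out_dir) {
  if (is.null(consensus) && is.null(region_diff) && is.null(sc_contrast)) {
    stopf("at least one stage output is required")
  }
  universes <- list()
  if (!is.null(consensus)) universes$consensus <- rownames(consensus$tiers)
  if (!is.null(region_diff)) universes$region <- region_diff$gene
  if (!is.null(sc_contrast)) universes$sc <- sc_contrast$gene
  if (length(universes) > 1L) {
    shared <- Reduce(intersect, universes)
    if (!length(shared)) {
      stopf("stage outputs have conflicting (disjoint) gene universes")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c("# GPCRome analysis report", "")
  if (!is.null(consensus)) {
    cfg <- consensus$config
    memb <- consensus$membership
    lines <- c(lines, "## Consensus core receptor set", "",
               sprintf("Rule: tier >= %s in >= %d%% of %d datasets; rescue %s (GM: %s, WM: %s).",
                       cfg$min_tier, round(cfg$min_fraction * 100),
                       ncol(consensus$tiers),
                       if (cfg$rescue_enabled) "enabled" else "disabled",
                       consensus$gm_dataset %||% "-",
                       consensus$wm_dataset %||% "-"),
               "",
               sprintf("Members: %d of %d catalog receptor genes (%d WM-rescued).",
                       sum(memb$consensus_member), nrow(memb),
                       sum(memb$rescued)), "",
               "| gene | tiers | support | member | flag |",
               "|---|---|---|---|---|")
    sel <- which(memb$consensus_member)
    for (i in sel) {
      lines <- c(lines, sprintf("| %s | %s | %d/%d | yes | %s |",
                                memb$gene[i],
                                paste(vapply(consensus$tiers[i, , drop = FALSE],
                                             as.character, ""), collapse = ","),
                                memb$n_support[i], ncol(consensus$tiers),
                                if (memb$rescued[i]) "WM-rescued" else ""))
    }
    lines <- c(lines, "")
    write_consensus(consensus, file.path(out_dir, "consensus_tiers.tsv"),
                    file.path(out_dir, "consensus_summary.json"))
  }
  if (!is.null(region_diff)) {
    calls <- region_diff[region_diff$direction != "none", , drop = FALSE]
    lines <- c(lines, "## Regional differential (WM vs GM)", "",
               sprintf("%d of %d genes called at the %.1f-fold threshold (%s mode).",
                       nrow(calls), nrow(region_diff),
                       attr(region_diff, "fc_threshold"),
                       if (isTRUE(attr(region_diff, "paired"))) "paired"
                       else "group-wise"),
               "", "| gene | log2FC | direction | q |", "|---|---|---|---|")
    for (i in seq_len(nrow(calls))) {
      lines <- c(lines, sprintf("| %s | %.3f | %s | %s |", calls$gene[i],
                                calls$log2_fold_change[i], calls$direction[i],
                                ifelse(is.na(calls$q_value[i]), "-",
                                       sprintf("%.3g", calls$q_value[i]))))
    }
    lines <- c(lines, "")
    write_region_diff(region_diff, file.path(out_dir, "region_diff.tsv"),
                      file.path(out_dir, "region_diff_config.json"))
  }
  if (!is.null(sc_contrast)) {
    calls <- sc_contrast[sc_contrast$direction != "none", , drop = FALSE]
    lines <- c(lines,
               sprintf("## Single-cell contrast: %s vs %s",
                       attr(sc_contrast, "cluster_a"),
                       attr(sc_contrast, "cluster_b")), "",
               sprintf("%d of %d panel genes called (|FC| >= %.2g, q < %.2g).",
                       nrow(calls), nrow(sc_contrast),
                       attr(sc_contrast, "fc_threshold"),
                       attr(sc_contrast, "alpha")),
               "", "| gene | log2FC | direction | q |", "|---|---|---|---|")
    for (i in seq_len(nrow(calls))) {
      lines <- c(lines, sprintf("| %s | %.3f | %s | %.3g |", calls$gene[i],
                                calls$log2_fold_change[i], calls$direction[i],
                                calls$q_value[i]))
    }
    lines <- c(lines, "")
    tsv <- file.path(out_dir, "sc_contrast.tsv")
    utils::write.table(as.data.frame(sc_contrast), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  report_path <- file.path(out_dir, "report.md")
  con <- file(report_path, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(report_path)
}
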