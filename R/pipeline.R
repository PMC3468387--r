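#' Pipeline configuration
#'
#' Paths and thresholds for the end-to-end authentication pipeline:
#' QC (Illumina) -> hit classification -> contamination filtering ->
#' damage profiling -> optional 5'-trimming bookkeeping -> divergence
#' (Illumina). Alignments are supplied as SAM files (produced by an
#' external aligner run with [recommend_parameters()], or by
#' [write_truth_sam()] in validation settings).
#'
#' @param platform `"illumina"` or `"helicos"`.
#' @param reads_fastq Path to the input FASTQ.
#' @param target_sam Path to alignments against the target genome.
#' @param contaminant_sam Optional path to alignments against the
#'   contaminant genome.
#' @param outgroup_sam Optional path to alignments against a distant
#'   outgroup genome (spurious-hit monitor).
#' @param out_dir Output directory (created if needed).
#' @param mapq_min Minimum mapping quality for high-quality hits.
#' @param qc A [qc_config()], applied to Illumina reads.
#' @param filter_mode `"strict"` or `"besthit"`.
#' @param contaminant_mode Contaminant-hit mode for the strict filter.
#' @param profile_window Terminal window of the misincorporation table.
#' @param bq_grid Base-quality grid for the divergence curve (Illumina).
#' @param end_mask End masking for divergence estimates.
#' @param trim Optional list (`n_bases`, `min_length`, and optionally
#'   `posttrim_sam`, `posttrim_contaminant_sam`) enabling the damage-trim
#'   stage.
#' @param seed Integer seed (recorded in the summary; the pipeline itself
#'   is deterministic given its inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(platform, reads_fastq, target_sam,
                            contaminant_sam = NULL, outgroup_sam = NULL,
                            out_dir = "paleomapr_run", mapq_min = 25,
                            qc = qc_config(), filter_mode = c("strict", "besthit"),
                            contaminant_mode = c("any_hit", "hq_hit"),
                            profile_window = 15,
                            bq_grid = seq(0, 40, by = 5), end_mask = 5,
                            trim = NULL, seed = 1L) {
  platform <- match_platform(platform)
  filter_mode <- match.arg(filter_mode)
  contaminant_mode <- match.arg(contaminant_mode)
  structure(
    list(platform = platform, reads_fastq = reads_fastq,
         target_sam = target_sam, contaminant_sam = contaminant_sam,
         outgroup_sam = outgroup_sam, out_dir = out_dir,
         mapq_min = mapq_min, qc = qc, filter_mode = filter_mode,
         contaminant_mode = contaminant_mode,
         profile_window = profile_window, bq_grid = bq_grid,
         end_mask = end_mask, trim = trim, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

require_input <- function(path, stage) {
  if (is.null(path) || !file.exists(path)) {
    stop("pipeline stage '", stage, "': missing input ",
         if (is.null(path)) "(not configured)" else path, call. = FALSE)
  }
  path
}

tsv_write <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the authentication pipeline
#'
#' Executes every configured stage, writes each intermediate in its
#' standard format under `out_dir` (FASTQ, TSV tables, JSON summary) and
#' returns the stage counts. Counts are monotone non-increasing through
#' the read filters, and a rerun on the same inputs is byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(platform = cfg$platform, seed = cfg$seed)

  ## --- qc -------------------------------------------------------------
  reads <- read_fastq(require_input(cfg$reads_fastq, "qc"), cfg$platform)
  summary$n_reads_input <- nrow(reads)
  if (cfg$platform == "illumina") {
    reads <- run_qc(reads, cfg$qc)
    tsv_write(attr(reads, "qc_summary"), file.path(cfg$out_dir, "qc_summary.tsv"))
    write_fastq(reads, file.path(cfg$out_dir, "reads_qc.fastq"))
  } else {
    reads <- length_filter(reads, cfg$qc$min_length)
  }
  summary$n_reads_after_qc <- nrow(reads)

  ## --- classification and contamination filtering ---------------------
  target <- read_sam(require_input(cfg$target_sam, "filter"))
  cls <- classify_hits(target, cfg$mapq_min,
                       exclude_duplicates = cfg$platform == "illumina")
  summary$n_target_records <- nrow(target)
  summary$n_hq_target <- sum(cls$status == "hq_endogenous")

  retained <- cls$read_id[cls$status == "hq_endogenous"]
  if (!is.null(cfg$contaminant_sam)) {
    contaminant <- read_sam(require_input(cfg$contaminant_sam, "filter"))
    retained <- if (cfg$filter_mode == "strict") {
      strict_filter(target, contaminant, cfg$contaminant_mode, cfg$mapq_min,
                    exclude_duplicates = cfg$platform == "illumina")
    } else {
      besthit_filter(target, contaminant, cfg$mapq_min,
                     exclude_duplicates = cfg$platform == "illumina")
    }
    cls$status[cls$status == "hq_endogenous" &
                 !cls$read_id %in% retained] <- "filtered_contaminant"
    cls$reason[cls$status == "filtered_contaminant"] <-
      paste0("excluded by ", cfg$filter_mode, " contaminant criterion")
  }
  tsv_write(cls, file.path(cfg$out_dir, "classification.tsv"))
  writeLines(retained, file.path(cfg$out_dir, "retained_read_ids.txt"))
  summary$n_retained <- length(retained)

  ## --- spurious-hit monitor -------------------------------------------
  if (!is.null(cfg$outgroup_sam)) {
    outgroup <- read_sam(require_input(cfg$outgroup_sam, "spurious"))
    sp <- spurious_rate(reads, outgroup, cfg$mapq_min)
    tsv_write(sp$size_histogram, file.path(cfg$out_dir, "spurious_sizes.tsv"))
    summary$n_spurious_outgroup <- sp$count
    summary$spurious_rate <- sp$rate
  }

  ## --- damage profile --------------------------------------------------
  kept_hits <- target[target$read_id %in% retained, , drop = FALSE]
  columns <- reconstruct_columns(kept_hits)
  profile <- accumulate_profile(columns, cfg$profile_window)
  tsv_write(profile, file.path(cfg$out_dir, "misincorporation.tsv"))
  summary$terminal_gc_at_fraction <-
    cumulative_terminal_damage(accumulate_profile(columns, Inf))

  ## --- damage trimming bookkeeping -------------------------------------
  if (!is.null(cfg$trim)) {
    failed <- reads[!reads$read_id %in% retained, , drop = FALSE]
    tr <- trim_candidates(failed, cfg$trim$n_bases,
                          cfg$trim$min_length %||% 30)
    write_fastq(tr$reads, file.path(cfg$out_dir, "trimmed.fastq"))
    summary$n_trim_candidates <- nrow(tr$records)
    if (!is.null(cfg$trim$posttrim_sam)) {
      post <- read_sam(require_input(cfg$trim$posttrim_sam, "trim-report"))
      recs <- classify_trimmed(tr$records, post,
                               read_reference(require_input(
                                 cfg$trim$reference_fasta, "trim-report")))
      newly <- hq_ids(post, cfg$mapq_min, exclude_duplicates = FALSE)
      if (!is.null(cfg$trim$posttrim_contaminant_sam)) {
        post_cont <- read_sam(cfg$trim$posttrim_contaminant_sam)
        cont <- if (!is.null(cfg$contaminant_sam)) {
          read_sam(cfg$contaminant_sam)
        } else {
          empty_hits()
        }
        newly <- conservative_posttrim_filter(cont, post_cont, newly)
      }
      gains <- gain_report(recs, newly, baseline_hq = summary$n_retained)
      tsv_write(recs, file.path(cfg$out_dir, "trim_records.tsv"))
      tsv_write(gains, file.path(cfg$out_dir, "trim_gains.tsv"))
      summary$n_trim_recovered <- sum(gains$n_recovered)
    }
  }

  ## --- divergence -------------------------------------------------------
  if (cfg$platform == "illumina" && nrow(columns) > 0 &&
      any(!is.na(columns$base_qual))) {
    curve <- divergence_curve(columns, cfg$bq_grid, cfg$end_mask)
    tsv_write(curve, file.path(cfg$out_dir, "divergence.tsv"))
    top <- curve[nrow(curve), ]
    summary$divergence_top_bq <- top$divergence
  }

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(cfg$out_dir, "summary.json"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
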