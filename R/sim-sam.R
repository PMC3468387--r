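#' Truth alignments as a hit table / SAM file
#'
#' Converts a simulation result into alignment records with CIGAR, MD and
#' NM computed exactly from the injected event list (`XT:A:U`, `X0:i:1`,
#' `X1:i:0`, MAPQ 37). With `reference` set to a *different* genome that
#' is coordinate-homologous to the simulated one (substitution-only
#' divergence, e.g. from [make_diverged_reference()]), the MD/NM fields
#' are recomputed against that genome at the true coordinates — the
#' standard way to build contaminant-genome alignments for filter tests.
#'
#' @param sim A `sim_result` from [simulate_reads()].
#' @param reference Optional named character vector to re-reference the
#'   alignments against (default: the simulated events themselves).
#' @param mapq Mapping quality to emit (default 37).
#' @return `truth_hits()`: a hit table as from [read_sam()];
#'   `write_truth_sam()` writes it as SAM and returns the path invisibly.
#' @export
truth_hits <- function(sim, reference = NULL, mapq = 37L) {
  truth <- sim$truth
  if ("polyT_trimmed" %in% names(truth)) {
    truth <- truth[!truth$polyT_trimmed, , drop = FALSE]
  }
  reads <- sim$reads[match(truth$read_id, sim$reads$read_id), , drop = FALSE]
  ev_by_read <- split(sim$events, sim$events$read_id)

  n <- nrow(truth)
  out_cigar <- character(n); out_md <- character(n); out_nm <- integer(n)
  out_seq <- character(n); out_qual <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    fields <- truth_sam_fields(
      bases = reads$bases[i], qual = reads$qual[i],
      events = ev_by_read[[truth$read_id[i]]],
      chrom = truth$source_sequence[i], strand = truth$strand[i],
      start = truth$start[i], end = truth$end[i], reference = reference
    )
    out_cigar[i] <- fields$cigar; out_md[i] <- fields$md
    out_nm[i] <- fields$nm; out_seq[i] <- fields$seq
    out_qual[i] <- fields$qual
  }
  hits <- tibble(
    read_id = truth$read_id,
    flag = ifelse(truth$strand == "reverse", 16L, 0L),
    reference_name = truth$source_sequence,
    position = as.integer(truth$start),
    mapq = as.integer(mapq),
    cigar = out_cigar, seq = out_seq, qual = out_qual,
    strand = truth$strand, uniqueness = "unique",
    best_hits = 1L, alt_hits = 0L, nm = out_nm, md = out_md,
    is_duplicate = FALSE
  )
  attr(hits, "header") <- "@HD\tVN:1.6\tSO:unsorted"
  hits
}

#' @rdname truth_hits
#' @param path Output SAM path.
#' @param ref_lengths Optional named integer vector used to emit `@SQ`
#'   header lines.
#' @export
write_truth_sam <- function(sim, path, reference = NULL, mapq = 37L,
                            ref_lengths = NULL) {
  hits <- truth_hits(sim, reference = reference, mapq = mapq)
  header <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(reference) && is.null(ref_lengths)) {
    ref_lengths <- nchar(reference)
  }
  if (!is.null(ref_lengths)) {
    header <- c(header, paste0("@SQ\tSN:", names(ref_lengths),
                               "\tLN:", ref_lengths))
  }
  write_sam(hits, path, header = header)
  invisible(path)
}

## Build SAM CIGAR/MD/NM/SEQ for one read from its event list.
truth_sam_fields <- function(bases, qual, events, chrom, strand, start, end,
                             reference = NULL) {
  chars <- explode_chars(bases)
  L <- length(chars)
  subs <- if (is.null(events)) NULL else
    events[events$type %in% c("substitution", "deamination"), , drop = FALSE]
  ins <- if (is.null(events)) NULL else
    events[events$type == "insertion", , drop = FALSE]
  dels <- if (is.null(events)) NULL else
    events[events$type == "deletion", , drop = FALSE]

  ## read-base columns (one per read base), in read orientation
  is_ins <- rep(FALSE, L)
  if (!is.null(ins) && nrow(ins) > 0) is_ins[ins$read_pos] <- TRUE
  base_ref <- chars
  if (!is.null(subs) && nrow(subs) > 0) base_ref[subs$read_pos] <- subs$ref_base
  base_ref[is_ins] <- NA_character_
  op <- ifelse(is_ins, "I", "M")
  ref_b <- base_ref
  read_b <- chars
  key <- as.numeric(seq_len(L))

  ## interleave deletion columns just before their anchoring read base
  if (!is.null(dels) && nrow(dels) > 0) {
    nd <- nrow(dels)
    # successive deletions at one anchor keep event order (template order)
    dkey <- dels$read_pos - 1 + seq_len(nd) / (nd + 1)
    op <- c(op, rep("D", nd))
    ref_b <- c(ref_b, dels$ref_base)
    read_b <- c(read_b, rep(NA_character_, nd))
    key <- c(key, dkey)
    ord0 <- order(key)
    op <- op[ord0]; ref_b <- ref_b[ord0]; read_b <- read_b[ord0]
  }
  n_cols <- length(op)

  ## template index of each reference-consuming column -> true coordinate
  consumes <- op %in% c("M", "D")
  tmpl_idx <- cumsum(consumes)
  ref_pos <- rep(NA_integer_, n_cols)
  ref_pos[consumes] <- if (strand == "forward") {
    start + tmpl_idx[consumes] - 1L
  } else {
    end - tmpl_idx[consumes] + 1L
  }
  if (!is.null(reference)) {
    contig <- reference[[chrom]]
    rb <- substring(contig, ref_pos[consumes], ref_pos[consumes])
    if (strand == "reverse") rb <- complement_chr(rb)
    ref_b[consumes] <- rb
  }

  ## flip to reference orientation for the SAM record
  if (strand == "reverse") {
    ord <- rev(seq_len(n_cols))
    op <- op[ord]
    ref_b <- complement_chr(ref_b[ord])
    read_b <- complement_chr(read_b[ord])
    seq_out <- revcomp_chr(bases)
    qual_out <- if (is.na(qual)) NA_character_ else reverse_chr(qual)
  } else {
    seq_out <- bases
    qual_out <- qual
  }

  mism <- op == "M" & ref_b != read_b
  nm <- sum(mism) + sum(op == "I") + sum(op == "D")

  ## CIGAR
  r <- rle(op)
  cigar <- paste0(r$lengths, r$values, collapse = "")

  ## MD over M/D columns in reference orientation
  md <- character(0)
  run <- 0L
  j <- 1L
  md_ops <- which(op != "I")
  while (j <= length(md_ops)) {
    i <- md_ops[j]
    if (op[i] == "M") {
      if (ref_b[i] == read_b[i]) {
        run <- run + 1L
      } else {
        md <- c(md, as.character(run), ref_b[i]); run <- 0L
      }
      j <- j + 1L
    } else { # deletion group
      md <- c(md, as.character(run)); run <- 0L
      grp <- character(0)
      while (j <= length(md_ops) && op[md_ops[j]] == "D") {
        grp <- c(grp, ref_b[md_ops[j]])
        j <- j + 1L
      }
      md <- c(md, paste0("^", paste(grp, collapse = "")))
    }
  }
  md <- paste(c(md, as.character(run)), collapse = "")

  list(cigar = cigar, md = md, nm = as.integer(nm), seq = seq_out,
       qual = qual_out)
}

#' Emulate aligner mappability on truth alignments
#'
#' A seed-and-extend aligner only reports alignments whose edit distance
#' is within the read-length-dependent maximum ([max_edit_distance()]).
#' This marks truth alignments exceeding that cap as unmapped, turning
#' exhaustive truth tables into realistic aligner output — e.g. when
#' building contaminant-genome alignments where only conserved-region
#' reads should map.
#'
#' @param hits A hit table from [truth_hits()].
#' @param per_base_error,missing_fraction Parameters of the edit-distance
#'   cap.
#' @return The hit table with over-cap rows converted to unmapped records.
#' @export
simulate_mappability <- function(hits, per_base_error = 0.02,
                                 missing_fraction = 0.04) {
  len <- nchar(hits$seq)
  cap <- max_edit_distance(pmax(len, 1L), per_base_error, missing_fraction)
  drop <- !is.na(hits$nm) & hits$nm > cap
  hits$flag[drop] <- bitwOr(hits$flag[drop], 4L)
  hits$uniqueness[drop] <- "unmapped"
  hits$position[drop] <- NA_integer_
  hits$cigar[drop] <- NA_character_
  hits$md[drop] <- NA_character_
  hits$nm[drop] <- NA_integer_
  hits$mapq[drop] <- 0L
  hits$best_hits[drop] <- NA_integer_
  hits$alt_hits[drop] <- NA_integer_
  hits
}

#' Generate a diverged copy of a reference
#'
#' Produces a substitution-only diverged genome at an exact nominal
#' divergence: `round(d * n_mutable)` positions are mutated, half by
#' transversion and half by transition, with transitions split evenly
#' between A/T-source and C/G-source sites so the two transition classes
#' (AT->GC, GC->AT) are balanced — the configuration under which the
#' damage-aware divergence statistic is unbiased. A `conserved` interval
#' can be held identical to emulate an ultra-conserved block shared
#' across genomes.
#'
#' @param reference Named character vector (single sequence).
#' @param divergence Target per-site divergence.
#' @param conserved Optional `c(start, end)` interval left untouched.
#' @param seed Integer seed.
#' @param name Name of the diverged sequence.
#' @param classes `"mixed"` (default): half transitions, half
#'   transversions. `"transversion"`: all divergence carried by
#'   transversions — every diverged site then contributes unit weight to
#'   the divergence statistic, so its binomial confidence interval is
#'   exactly calibrated (the AT->GC doubling otherwise inflates the
#'   statistic's sampling variance 1.5-fold over binomial).
#' @param min_spacing Minimum distance between diverged sites. Spacing
#'   sites beyond the read length makes per-site coverages independent
#'   (no read straddles two diverged sites), removing the cluster-sampling
#'   design effect that would otherwise widen the divergence estimator's
#'   true sampling noise beyond its nominal binomial interval.
#' @return Named character vector of length 1.
#' @export
make_diverged_reference <- function(reference, divergence, conserved = NULL,
                                    seed = 1L, name = names(reference)[1],
                                    classes = c("mixed", "transversion"),
                                    min_spacing = 0) {
  classes <- match.arg(classes)
  stopifnot(length(reference) == 1, divergence >= 0, divergence < 1)
  with_sim_seed(seed, {
    chars <- explode_chars(reference[[1]])
    mutable <- which(chars %in% DNA_BASES)
    if (!is.null(conserved)) {
      mutable <- setdiff(mutable, conserved[1]:conserved[2])
    }
    m <- round(divergence * length(mutable))
    if (m == 0) return(stats::setNames(reference[[1]], name))
    if (min_spacing > 0) {
      # uniform hard-core placement: sorted draws on a shrunk axis, then
      # shifted apart by the spacing
      span <- length(chars) - (m - 1L) * min_spacing
      stopifnot(span > m)
      base_pos <- sort(sample.int(span, m)) + (0:(m - 1L)) * min_spacing
      mutable <- intersect(base_pos, mutable)
      m <- length(mutable)
    }
    m_ts <- if (classes == "transversion") 0L else round(m / 2)
    m_tv <- m - m_ts
    at_pool <- mutable[chars[mutable] %in% c("A", "T")]
    gc_pool <- mutable[chars[mutable] %in% c("C", "G")]
    ts_at <- sample(at_pool, min(round(m_ts / 2), length(at_pool)))
    ts_gc <- sample(setdiff(gc_pool, ts_at), min(m_ts - length(ts_at),
                                                 length(gc_pool)))
    ts_sites <- c(ts_at, ts_gc)
    tv_sites <- sample(setdiff(mutable, ts_sites), m_tv)
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    chars[ts_sites] <- transition[chars[ts_sites]]
    tv_map <- list(A = c("C", "T"), C = c("A", "G"),
                   G = c("C", "T"), T = c("A", "G"))
    pick <- runif(length(tv_sites)) < 0.5
    chars[tv_sites] <- vapply(seq_along(tv_sites), function(j) {
      tv_map[[chars[tv_sites[j]]]][1 + pick[j]]
    }, character(1))
    stats::setNames(paste(chars, collapse = ""), name)
  })
}
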