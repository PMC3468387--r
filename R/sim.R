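#' Simulation configuration
#'
#' Parameters of the platform-aware read simulator. Defaults emulate the
#' Helicos tSMS error profile: per-base insertion rate 1.5% and deletion
#' rate 3% (manufacturer-reported), with substitution error explored over
#' 0–1.5%. Read lengths default to the 25–57 nt range typical of ancient
#' single-molecule reads; an optional ancient-damage overlay deaminates
#' template cytosines near the 5' terminus with geometrically decaying
#' probability (an extension beyond the error-only simulator, off by
#' default).
#'
#' @param platform `"helicos"` (no base qualities) or `"illumina"`.
#' @param length_range Inclusive uniform read-length range, used when
#'   `length_distribution` is `NULL`.
#' @param length_distribution Optional tibble (`length`, `prob`) giving an
#'   empirical length histogram.
#' @param insertion_rate Per-emitted-base insertion probability.
#' @param deletion_rate Per-traversed-reference-base deletion probability.
#' @param substitution_rate Per-base substitution-error probability.
#' @param base_composition Named probability vector over A/C/G/T used for
#'   inserted and substituting bases.
#' @param pwm Optional 11x4 position weight matrix (rows are positions
#'   -5..+5 around the start site) biasing start-site sampling; `NULL`
#'   samples uniformly.
#' @param damage List with `p0` (deamination probability at 5' position
#'   1), `decay` (geometric decay per position) and `max_overhang`
#'   (furthest affected position). `p0 = 0` disables the overlay.
#' @param polyT_trim Emulate the instrument-side trimming of reads
#'   starting with two or more thymines (poly-A tail read-through).
#' @param bq_high,bq_low,low_q_frac,low_q_sub_rate Two-level base-quality
#'   model for Illumina-profile reads: every base gets `bq_high` except a
#'   random `low_q_frac` fraction which get `bq_low` and an extra
#'   substitution-error probability of `low_q_sub_rate`.
#' @param seed Integer seed; every stochastic step in the simulator draws
#'   from one seeded stream, so runs are fully reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(platform = c("helicos", "illumina"),
                       length_range = c(25, 57),
                       length_distribution = NULL,
                       insertion_rate = 0.015,
                       deletion_rate = 0.03,
                       substitution_rate = 0.005,
                       base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       pwm = NULL,
                       damage = list(p0 = 0, decay = 0.5, max_overhang = 10),
                       polyT_trim = FALSE,
                       bq_high = 40, bq_low = 10,
                       low_q_frac = 0, low_q_sub_rate = 0,
                       seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(
    insertion_rate >= 0, insertion_rate <= 1,
    deletion_rate >= 0, deletion_rate <= 1,
    substitution_rate >= 0, substitution_rate <= 1,
    length(base_composition) == 4, abs(sum(base_composition) - 1) < 1e-8,
    damage$p0 >= 0, damage$p0 <= 1, damage$decay > 0, damage$decay <= 1
  )
  if (!is.null(pwm)) validate_pwm(pwm)
  if (!is.null(length_distribution)) {
    stopifnot(all(c("length", "prob") %in% names(length_distribution)),
              all(length_distribution$prob >= 0),
              abs(sum(length_distribution$prob) - 1) < 1e-8)
  }
  names(base_composition) <- DNA_BASES
  structure(
    list(platform = platform, length_range = length_range,
         length_distribution = length_distribution,
         insertion_rate = insertion_rate, deletion_rate = deletion_rate,
         substitution_rate = substitution_rate,
         base_composition = base_composition, pwm = pwm, damage = damage,
         polyT_trim = polyT_trim, bq_high = bq_high, bq_low = bq_low,
         low_q_frac = low_q_frac, low_q_sub_rate = low_q_sub_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

validate_pwm <- function(pwm) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 11, ncol(pwm) == 4,
            all(pwm >= 0), all(abs(rowSums(pwm) - 1) < 1e-8))
  invisible(pwm)
}

with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

draw_bases <- function(n, composition) {
  if (n == 0) return(character(0))
  DNA_BASES[sample.int(4, n, replace = TRUE, prob = composition)]
}

## Draw a substituting base different from `orig`, per composition.
draw_substitutes <- function(orig, composition) {
  out <- character(length(orig))
  for (b in DNA_BASES) {
    idx <- which(orig == b)
    if (length(idx) == 0) next
    p <- composition
    p[b] <- 0
    if (sum(p) == 0) p <- setNames(rep(1, 4), DNA_BASES) * (DNA_BASES != b)
    out[idx] <- DNA_BASES[sample.int(4, length(idx), replace = TRUE, prob = p)]
  }
  out
}

draw_lengths <- function(n, cfg) {
  if (!is.null(cfg$length_distribution)) {
    ld <- cfg$length_distribution
    ld$length[sample.int(nrow(ld), n, replace = TRUE, prob = ld$prob)]
  } else {
    sample(cfg$length_range[1]:cfg$length_range[2], n, replace = TRUE)
  }
}

#' Build a start-site position weight matrix
#'
#' Column-wise base frequencies of the 11-mer contexts (positions -5..+5
#' around the 5' terminus) of observed hits, with an additive pseudocount.
#'
#' @param contexts Character vector of 11-mers over A/C/G/T.
#' @param pseudocount Additive count per cell (default 0).
#' @return An 11x4 matrix, rows summing to 1, columns named A/C/G/T.
#' @export
build_pwm <- function(contexts, pseudocount = 0) {
  if (length(contexts) == 0 && pseudocount == 0) {
    stop("cannot build a PWM from no contexts with zero pseudocount",
         call. = FALSE)
  }
  stopifnot(all(nchar(contexts) == 11))
  mat <- matrix(pseudocount, nrow = 11, ncol = 4,
                dimnames = list(as.character(-5:5), DNA_BASES))
  if (length(contexts) > 0) {
    chars <- matrix(explode_chars(toupper(contexts)), nrow = 11)
    for (i in 1:11) {
      tab <- table(factor(chars[i, ], levels = DNA_BASES))
      mat[i, ] <- mat[i, ] + as.integer(tab)
    }
  }
  sweep(mat, 1, rowSums(mat), "/")
}

pwm_score <- function(pwm, contexts) {
  chars <- matrix(match(explode_chars(contexts), DNA_BASES), nrow = 11)
  apply(chars, 2, function(ix) prod(pwm[cbind(1:11, ix)]))
}

merged_sequences <- function(reference) {
  stats::setNames(paste0(reference, revcomp_chr(reference)), names(reference))
}

#' Sample read start sites
#'
#' Start sites are drawn on each chromosome's merged strand sequence
#' (forward followed by reverse complement) with probability proportional
#' to the PWM likelihood of the 11-mer context centred on the site
#' (uniform for a flat or absent PWM), implemented by rejection sampling
#' against the maximum attainable PWM score. Coordinates are mapped back
#' to forward-strand positions of the 5' terminus plus a strand flag.
#'
#' @param reference Named character vector of sequences.
#' @param pwm 11x4 PWM or `NULL` for uniform sampling.
#' @param n Number of sites.
#' @param seed Integer seed.
#' @return A tibble with `reference_name`, `position` (forward-strand
#'   coordinate of the 5' start base), `strand`.
#' @export
sample_start_sites <- function(reference, pwm = NULL, n = 1, seed = 1L) {
  if (any(nchar(reference) < 11)) {
    stop("reference sequences must be at least 11 nt for context scoring",
         call. = FALSE)
  }
  with_sim_seed(seed, {
    sites <- draw_start_sites(reference, pwm, n)
    lens <- nchar(reference)[sites$chrom]
    fwd <- sites$merged_pos <= lens
    tibble(
      reference_name = sites$chrom,
      position = ifelse(fwd, sites$merged_pos,
                        2L * lens - sites$merged_pos + 1L),
      strand = ifelse(fwd, "forward", "reverse")
    )
  })
}

## Internal: merged-coordinate start sites (chrom, merged_pos), PWM-biased.
draw_start_sites <- function(reference, pwm, n) {
  merged <- merged_sequences(reference)
  mlens <- nchar(merged)
  if (!is.null(pwm)) validate_pwm(pwm)
  max_score <- if (is.null(pwm)) 1 else prod(apply(pwm, 1, max))
  chrom <- character(0)
  pos <- integer(0)
  guard <- 0L
  while (length(pos) < n) {
    guard <- guard + 1L
    if (guard > 10000L) {
      stop("start-site rejection sampling failed to converge", call. = FALSE)
    }
    need <- n - length(pos)
    batch <- max(need * 2L, 100L)
    ch <- names(merged)[sample.int(length(merged), batch, replace = TRUE,
                                   prob = mlens)]
    ## a start needs 5 context bases on each side within the merged strand
    p <- 6L + floor(runif(batch) * (mlens[ch] - 10L))
    p <- as.integer(p)
    if (is.null(pwm)) {
      acc <- rep(TRUE, batch)
    } else {
      ctx <- substring(merged[ch], p - 5L, p + 5L)
      ok <- !grepl("N", ctx, fixed = TRUE)
      sc <- rep(0, batch)
      if (any(ok)) sc[ok] <- pwm_score(pwm, ctx[ok])
      acc <- runif(batch) < sc / max_score
    }
    chrom <- c(chrom, ch[acc])
    pos <- c(pos, p[acc])
  }
  list(chrom = chrom[seq_len(n)], merged_pos = pos[seq_len(n)])
}

#' Simulate platform-profile reads with truth alignments
#'
#' Reads are emitted from sampled start sites on the merged strand
#' sequence: each emitted base is an insertion with probability
#' `insertion_rate` (base drawn from the base composition); otherwise the
#' next reference base is taken after discarding each successive
#' reference base with probability `deletion_rate`, and is replaced by a
#' substituting base with probability `substitution_rate`. The damage
#' overlay is applied to the template before sequencing error: a template
#' cytosine at 5' position i is read as thymine with probability
#' `p0 * decay^(i-1)` up to `max_overhang`. Reads containing N or
#' overlapping the junction between the two strand sequences are
#' discarded and resampled. Every injected event is recorded in the truth
#' tables.
#'
#' @param reference Named character vector of sequences.
#' @param cfg A [sim_config()].
#' @param n Number of reads.
#' @param id_prefix Prefix for generated read ids.
#' @return A list of class `sim_result`:
#' \describe{
#'   \item{reads}{read table (qualities present for Illumina profile)}
#'   \item{truth}{tibble `read_id`, `source_sequence`, `strand`, `start`,
#'     `end` (1-based inclusive forward-strand coordinates of the aligned
#'     reference span)}
#'   \item{events}{tibble `read_id`, `read_pos`, `type` (`substitution`,
#'     `insertion`, `deletion`, `deamination`), `ref_base`, `read_base`,
#'     in sequenced-strand orientation; deletions are anchored to the read
#'     position following the deleted base}
#'   \item{n_emitted, n_inserted, n_traversed, n_deleted, n_substituted}{
#'     realized event totals for rate checks}
#' }
#' @export
simulate_reads <- function(reference, cfg = sim_config(), n,
                           id_prefix = "sim") {
  stopifnot(n >= 1)
  max_len <- if (!is.null(cfg$length_distribution)) {
    max(cfg$length_distribution$length)
  } else {
    cfg$length_range[2]
  }
  ## worst realistic template need; resampling handles the tail
  if (all(nchar(reference) < max_len + 10)) {
    stop("reference too short for the configured read lengths", call. = FALSE)
  }
  with_sim_seed(cfg$seed, {
    merged <- merged_sequences(reference)
    flens <- nchar(reference)
    done <- list()
    pending <- n
    rounds <- 0L
    totals <- c(n_emitted = 0, n_inserted = 0, n_traversed = 0,
                n_deleted = 0, n_substituted = 0)
    while (pending > 0) {
      rounds <- rounds + 1L
      if (rounds > 200L) {
        stop("read simulation failed to place reads; reference may be ",
             "infeasible for the configured lengths", call. = FALSE)
      }
      batch <- sim_batch(merged, flens, cfg, pending)
      if (!is.null(batch)) {
        done[[length(done) + 1L]] <- batch
        totals <- totals + batch$totals
        pending <- pending - batch$n
      }
    }
    assemble_sim_result(done, cfg, id_prefix, totals)
  })
}

## One attempt at `m` reads; returns the subset that landed on a valid
## (junction-free, N-free) template, with all event draws materialized.
sim_batch <- function(merged, flens, cfg, m) {
  L <- draw_lengths(m, cfg)
  sites <- draw_start_sites(
    stats::setNames(substring(merged, 1, flens), names(flens)), cfg$pwm, m)
  ## (draw_start_sites scores contexts on the merged sequence internally)
  total <- sum(L)
  read_idx <- rep.int(seq_len(m), L)
  emit_pos <- sequence(L)
  is_ins <- runif(total) < cfg$insertion_rate
  n_del_before <- integer(total)
  nri <- sum(!is_ins)
  if (cfg$deletion_rate > 0 && nri > 0) {
    n_del_before[!is_ins] <- stats::rgeom(nri, 1 - cfg$deletion_rate)
  }
  consumed <- ifelse(is_ins, 0L, n_del_before + 1L)
  ## template index of each emitted reference base (position in fragment):
  ## per-read cumulative consumption, via a global cumsum minus offsets
  ends <- cumsum(L)
  starts <- ends - L + 1L
  tot <- cumsum(consumed)
  base_off <- c(0L, tot[ends])[seq_len(m)]
  cons_cum <- tot - base_off[read_idx]
  tmpl_idx <- integer(total)
  tmpl_idx[!is_ins] <- cons_cum[!is_ins]
  R <- as.integer(tot[ends] - c(0L, tot[ends])[seq_len(m)])

  ## validity: template must fit inside one strand segment, no N
  ml <- nchar(merged)[sites$chrom]
  fl <- flens[sites$chrom]
  s <- sites$merged_pos
  fits <- R >= 1 &
    ifelse(s <= fl, s + R - 1 <= fl, s + R - 1 <= ml)
  tmpl <- rep(NA_character_, m)
  tmpl[fits] <- substring(merged[sites$chrom[fits]], s[fits],
                          s[fits] + R[fits] - 1)
  ok <- fits & !is.na(tmpl) & !grepl("N", tmpl, fixed = TRUE)
  if (!any(ok)) return(NULL)

  keep_read <- which(ok)
  sel <- read_idx %in% keep_read
  new_idx <- match(read_idx[sel], keep_read)
  build_reads(
    cfg = cfg,
    chrom = sites$chrom[keep_read],
    merged_start = s[keep_read],
    flen = fl[keep_read],
    tmpl = tmpl[keep_read],
    R = R[keep_read],
    L = L[keep_read],
    read_idx = new_idx,
    emit_pos = emit_pos[sel],
    is_ins = is_ins[sel],
    n_del_before = n_del_before[sel],
    tmpl_idx = tmpl_idx[sel]
  )
}

build_reads <- function(cfg, chrom, merged_start, flen, tmpl, R, L,
                        read_idx, emit_pos, is_ins, n_del_before, tmpl_idx) {
  m <- length(tmpl)
  total <- length(read_idx)
  tmpl_chars <- explode_chars(tmpl)
  tmpl_off <- c(0L, cumsum(R))[seq_len(m)]

  ## reference base under each emitted (non-inserted) read base
  ref_char <- rep(NA_character_, total)
  ref_char[!is_ins] <- tmpl_chars[tmpl_off[read_idx[!is_ins]] +
                                    tmpl_idx[!is_ins]]

  ## damage overlay: template C near the 5' terminus reads as T
  dmg <- rep(FALSE, total)
  if (cfg$damage$p0 > 0) {
    cand <- !is_ins & ref_char == "C" & tmpl_idx <= cfg$damage$max_overhang
    p <- cfg$damage$p0 * cfg$damage$decay^(tmpl_idx[cand] - 1)
    dmg[cand] <- runif(sum(cand)) < p
  }
  post_dmg <- ifelse(dmg, "T", ref_char)

  ## substitution errors (uniform, plus extra at low-quality bases)
  sub_p <- rep(cfg$substitution_rate, total)
  low_q <- rep(FALSE, total)
  if (cfg$platform == "illumina" && cfg$low_q_frac > 0) {
    low_q <- runif(total) < cfg$low_q_frac
    sub_p[low_q & !is_ins] <- 1 - (1 - sub_p[low_q & !is_ins]) *
      (1 - cfg$low_q_sub_rate)
  }
  is_sub <- !is_ins & runif(total) < sub_p
  read_char <- post_dmg
  if (any(is_sub)) {
    read_char[is_sub] <- draw_substitutes(post_dmg[is_sub],
                                          cfg$base_composition)
  }
  read_char[is_ins] <- draw_bases(sum(is_ins), cfg$base_composition)

  ## events ------------------------------------------------------------
  ev <- list()
  ins_i <- which(is_ins)
  if (length(ins_i) > 0) {
    ev$ins <- tibble(read = read_idx[ins_i], read_pos = emit_pos[ins_i],
                     type = "insertion", ref_base = NA_character_,
                     read_base = read_char[ins_i])
  }
  del_i <- which(n_del_before > 0)
  if (length(del_i) > 0) {
    reps <- n_del_before[del_i]
    del_tmpl <- unlist(lapply(seq_along(del_i), function(j) {
      i <- del_i[j]
      (tmpl_idx[i] - reps[j]):(tmpl_idx[i] - 1L)
    }), use.names = FALSE)
    del_read <- rep.int(read_idx[del_i], reps)
    ev$del <- tibble(read = del_read,
                     read_pos = rep.int(emit_pos[del_i], reps),
                     type = "deletion",
                     ref_base = tmpl_chars[tmpl_off[del_read] + del_tmpl],
                     read_base = NA_character_)
  }
  ## a damaged base substituted back to its genomic base is a net no-op
  sub_i <- which(is_sub & read_char != ref_char)
  if (length(sub_i) > 0) {
    ev$sub <- tibble(read = read_idx[sub_i], read_pos = emit_pos[sub_i],
                     type = "substitution", ref_base = ref_char[sub_i],
                     read_base = read_char[sub_i])
  }
  dmg_i <- which(dmg & !is_sub)
  if (length(dmg_i) > 0) {
    ev$dmg <- tibble(read = read_idx[dmg_i], read_pos = emit_pos[dmg_i],
                     type = "deamination", ref_base = "C", read_base = "T")
  }
  events <- dplyr::bind_rows(ev)
  if (nrow(events) > 0) events <- dplyr::arrange(events, .data$read,
                                                 .data$read_pos, .data$type)

  ## assemble base and quality strings ---------------------------------
  ends <- cumsum(L)
  starts <- ends - L + 1L
  all_chars <- paste(read_char, collapse = "")
  bases <- substring(all_chars, starts, ends)
  qual <- rep(NA_character_, m)
  if (cfg$platform == "illumina") {
    bq <- ifelse(low_q, cfg$bq_low, cfg$bq_high)
    qual <- substring(intToUtf8(bq + 33L), starts, ends)
  }

  fwd <- merged_start <= flen
  offset <- merged_start - flen
  truth <- tibble(
    source_sequence = chrom,
    strand = ifelse(fwd, "forward", "reverse"),
    start = ifelse(fwd, merged_start, flen - offset - R + 2L),
    end = ifelse(fwd, merged_start + R - 1L, flen - offset + 1L)
  )

  list(
    n = m,
    bases = unname(bases), qual = unname(qual), truth = truth,
    events = events,
    totals = c(n_emitted = total, n_inserted = length(ins_i),
               n_traversed = sum(R), n_deleted = sum(n_del_before),
               n_substituted = length(sub_i))
  )
}

assemble_sim_result <- function(done, cfg, id_prefix, totals) {
  n_per <- vapply(done, function(d) as.integer(d$n), integer(1))
  n <- sum(n_per)
  ids <- sprintf("%s_%06d", id_prefix, seq_len(n))
  id_off <- c(0L, cumsum(n_per))
  reads <- read_table(
    ids,
    unlist(lapply(done, `[[`, "bases"), use.names = FALSE),
    unlist(lapply(done, `[[`, "qual"), use.names = FALSE),
    cfg$platform
  )
  truth <- dplyr::bind_rows(lapply(done, `[[`, "truth"))
  truth <- dplyr::bind_cols(tibble(read_id = ids), truth)
  events <- dplyr::bind_rows(lapply(seq_along(done), function(b) {
    e <- done[[b]]$events
    if (is.null(e) || nrow(e) == 0) return(NULL)
    e$read_id <- ids[id_off[b] + e$read]
    dplyr::select(e, "read_id", "read_pos", "type", "ref_base", "read_base")
  }))
  if (nrow(events) == 0) {
    events <- tibble(read_id = character(0), read_pos = integer(0),
                     type = character(0), ref_base = character(0),
                     read_base = character(0))
  }
  if (cfg$polyT_trim) {
    trimmed <- polyT_start_trim(reads)
    reads <- trimmed$reads
    # coordinates/events of poly-T-trimmed reads are no longer truth-exact;
    # flag them so oracle tests can exclude them
    truth$polyT_trimmed <- truth$read_id %in% trimmed$trimmed_ids
  }
  structure(
    list(reads = reads, truth = truth, events = events,
         n_emitted = unname(totals["n_emitted"]),
         n_inserted = unname(totals["n_inserted"]),
         n_traversed = unname(totals["n_traversed"]),
         n_deleted = unname(totals["n_deleted"]),
         n_substituted = unname(totals["n_substituted"])),
    class = "sim_result"
  )
}

## Instrument-side emulation: reads starting with >= 2 thymines lose the
## leading thymine run (poly-A tail read-through on the template strand).
polyT_start_trim <- function(reads) {
  run <- attr(regexpr("^T+", reads$bases), "match.length")
  hit <- run >= 2
  reads$bases[hit] <- substring(reads$bases[hit], run[hit] + 1L)
  reads$qual[hit] <- ifelse(is.na(reads$qual[hit]), NA_character_,
                            substring(reads$qual[hit], run[hit] + 1L))
  list(reads = reads, trimmed_ids = reads$read_id[hit])
}

#' Simulate random (null) reads
#'
#' I.i.d. bases from a fixed composition with lengths drawn from an
#' empirical distribution restricted to lengths above 24 nt — the null
#' model used to gauge chance-alignment rates.
#'
#' @param base_composition Named probability vector over A/C/G/T.
#' @param length_distribution Tibble (`length`, `prob`); all lengths must
#'   exceed 24.
#' @param n Number of reads.
#' @param seed Integer seed.
#' @param id_prefix Prefix for read ids.
#' @return A read table (helicos platform label, no qualities).
#' @export
simulate_random_reads <- function(base_composition, length_distribution, n,
                                  seed = 1L, id_prefix = "rand") {
  stopifnot(all(length_distribution$length > 24),
            all(length_distribution$prob > 0))
  with_sim_seed(seed, {
    L <- length_distribution$length[
      sample.int(nrow(length_distribution), n, replace = TRUE,
                 prob = length_distribution$prob)]
    chars <- draw_bases(sum(L), base_composition)
    ends <- cumsum(L)
    bases <- substring(paste(chars, collapse = ""), ends - L + 1L, ends)
    read_table(sprintf("%s_%06d", id_prefix, seq_len(n)), bases,
               NA_character_, "helicos")
  })
}

#' Generate a random reference sequence
#'
#' @param n_bases Sequence length.
#' @param base_composition Named probability vector over A/C/G/T.
#' @param seed Integer seed.
#' @param name Sequence name.
#' @return A named character vector of length 1.
#' @export
random_reference <- function(n_bases, base_composition = c(A = 0.25, C = 0.25,
                                                           G = 0.25, T = 0.25),
                             seed = 1L, name = "chr1") {
  with_sim_seed(seed, {
    stats::setNames(paste(draw_bases(n_bases, base_composition),
                          collapse = ""), name)
  })
}
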