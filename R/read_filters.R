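# Steps 2-4 of the pipeline: repeat marking and removal, multi-mapping and
# a/b-version overlap resolution, and iterative remapping of unmapped reads
# after midpoint splitting.

#' Repeat filtering policy
#'
#' @param recognized_classes Repeat classes whose marks trigger removal rules.
#' @param min_unmarked_m Minimum unmarked aligned ('M') length in bp; below
#'   this the placement is removed.
#' @param overlap_residual Maximum non-overlapped 'M' length (bp) at which a
#'   partially overlapped a/b placement is removed.
#' @param remap_min_len Unmapped reads longer than this (bp) are split and
#'   remapped; fragments shorter than this are discarded.
#' @param extra_classes Additional class labels to recognize.
#' @return An object of class `bs_repeat_policy` (a list).
#' @export
repeat_policy <- function(recognized_classes = c("Alu", "simple repeats", "ERVL-MaLR",
                                                 "low-complexity", "L1HS", "L1M", "L1P",
                                                 "LTR ERV", "Segmental Dups", "CNVs"),
                          min_unmarked_m = 20, overlap_residual = 20,
                          remap_min_len = 35, extra_classes = character()) {
  stopifnot(min_unmarked_m > 0, overlap_residual > 0, remap_min_len > 0)
  structure(list(recognized_classes = union(recognized_classes, extra_classes),
                 min_unmarked_m = min_unmarked_m,
                 overlap_residual = overlap_residual,
                 remap_min_len = remap_min_len),
            class = "bs_repeat_policy")
}

# M-runs of each placement projected onto Watson coordinates.
# Returns a tibble: pidx, wstart, wend (0-based half-open).
placement_m_runs <- function(placements, lengths) {
  if (nrow(placements) == 0) {
    return(tibble::tibble(pidx = integer(), wstart = integer(), wend = integer()))
  }
  out_p <- vector("list", nrow(placements))
  for (i in seq_len(nrow(placements))) {
    ops <- cigar_ops(placements$cigar[i])
    tpos <- placements$aln_start[i]
    ws <- integer(0); we <- integer(0)
    for (j in seq_along(ops$op)) {
      if (ops$op[j] == "M") {
        ws <- c(ws, tpos); we <- c(we, tpos + ops$len[j]); tpos <- tpos + ops$len[j]
      } else if (ops$op[j] == "D") {
        tpos <- tpos + ops$len[j]
      }
    }
    if (placements$strand[i] == "C") {
      L <- unname(lengths[[placements$contig[i]]])
      tmp <- L - we
      we <- L - ws
      ws <- tmp
    }
    out_p[[i]] <- tibble::tibble(pidx = i, wstart = ws, wend = we)
  }
  dplyr::bind_rows(out_p)
}

#' Mark repeat overlaps on candidate placements
#'
#' Every aligned ('M') read position whose Watson reference position falls in
#' a recognized-class repeat interval is marked with that class. Adds columns
#' `n_classes` (distinct recognized classes touched), `marked_bp` (aligned
#' bases under recognized-class intervals), `repeat_overlap_bp` (aligned bases
#' under any annotated interval, used for multi-mapping resolution),
#' `unmarked_m` (aligned bases minus marked) and `classes` (comma-joined).
#'
#' @param placements Candidate placements from [map_reads()].
#' @param repeats Repeat intervals tibble ([read_repeat_bed()]).
#' @param policy [repeat_policy()].
#' @param lengths Named integer vector of contig lengths.
#' @return `placements` with the marking columns added.
#' @export
mark_repeats <- function(placements, repeats, policy = repeat_policy(),
                         lengths = NULL) {
  n <- nrow(placements)
  placements$n_classes <- integer(n)
  placements$marked_bp <- integer(n)
  placements$repeat_overlap_bp <- integer(n)
  placements$classes <- character(n)
  placements$unmarked_m <- placements$n_aligned
  if (n == 0 || is.null(repeats) || nrow(repeats) == 0) return(placements)
  if (is.null(lengths)) {
    lengths <- tapply(placements$ref_end, placements$contig, max)
  }
  runs <- placement_m_runs(placements, lengths)

  for (contig in unique(placements$contig)) {
    rep_c <- repeats[repeats$contig == contig, , drop = FALSE]
    if (nrow(rep_c) == 0) next
    run_c <- runs[placements$contig[runs$pidx] == contig, , drop = FALSE]
    if (nrow(run_c) == 0) next
    ir_runs <- IRanges::IRanges(start = run_c$wstart + 1L, end = run_c$wend)

    # overlap with the union of all annotated intervals (for Step 3 resolution)
    ir_all <- IRanges::reduce(IRanges::IRanges(start = rep_c$start + 1L, end = rep_c$end))
    ov <- IRanges::findOverlaps(ir_runs, ir_all)
    if (length(ov) > 0) {
      w <- IRanges::width(IRanges::pintersect(ir_runs[S4Vectors::queryHits(ov)],
                                              ir_all[S4Vectors::subjectHits(ov)]))
      bp <- tapply(w, run_c$pidx[S4Vectors::queryHits(ov)], sum)
      idx <- as.integer(names(bp))
      placements$repeat_overlap_bp[idx] <- placements$repeat_overlap_bp[idx] + as.integer(bp)
    }

    # per recognized class (intervals reduced within class to avoid double counting)
    for (cls in intersect(unique(rep_c$repeat_class), policy$recognized_classes)) {
      rc <- rep_c[rep_c$repeat_class == cls, , drop = FALSE]
      ir_cls <- IRanges::reduce(IRanges::IRanges(start = rc$start + 1L, end = rc$end))
      ov <- IRanges::findOverlaps(ir_runs, ir_cls)
      if (length(ov) == 0) next
      w <- IRanges::width(IRanges::pintersect(ir_runs[S4Vectors::queryHits(ov)],
                                              ir_cls[S4Vectors::subjectHits(ov)]))
      bp <- tapply(w, run_c$pidx[S4Vectors::queryHits(ov)], sum)
      idx <- as.integer(names(bp))
      placements$marked_bp[idx] <- placements$marked_bp[idx] + as.integer(bp)
      placements$n_classes[idx] <- placements$n_classes[idx] + 1L
      placements$classes[idx] <- ifelse(placements$classes[idx] == "", cls,
                                        paste(placements$classes[idx], cls, sep = ","))
    }
  }
  placements$unmarked_m <- placements$n_aligned - placements$marked_bp
  placements
}

#' Apply the repeat-removal rules to marked placements
#'
#' A placement is removed if it touches two or more different recognized
#' repeat classes ("two-repeat-types"), or if its unmarked aligned length is
#' below `policy$min_unmarked_m` ("short-unmarked-M").
#'
#' @param marked Output of [mark_repeats()].
#' @param policy [repeat_policy()].
#' @return `marked` with logical `keep` and character `reason` columns.
#' @export
filter_repeat_hit <- function(marked, policy = repeat_policy()) {
  reason <- rep(NA_character_, nrow(marked))
  reason[marked$unmarked_m < policy$min_unmarked_m] <- "short-unmarked-M"
  reason[marked$n_classes >= 2L] <- "two-repeat-types"
  marked$keep <- is.na(reason)
  marked$reason <- reason
  marked
}

#' Resolve multi-mapping placements of one tagged read
#'
#' Among the surviving placements of one (read, tag) pair, only the placement
#' with the shortest total overlap with annotated repeats is kept; ties are
#' broken by the aligner's deterministic order (contig, Watson start, Watson
#' strand before Crick).
#'
#' @param hits Marked, filter-passing placements of a single (read, tag) pair.
#' @return At most one row of `hits`.
#' @export
resolve_multimapping <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  ord <- order(hits$repeat_overlap_bp, hits$contig, hits$ref_start,
               match(hits$strand, c("W", "C")))
  hits[ord[1], , drop = FALSE]
}

# watson-axis M positions of a single placement, as an IRanges
placement_m_ir <- function(placement, lengths) {
  runs <- placement_m_runs(placement, lengths)
  IRanges::reduce(IRanges::IRanges(start = runs$wstart + 1L, end = runs$wend))
}

#' Resolve overlap between the 'a' and 'b' placements of one read
#'
#' If one version's aligned segments are totally covered by the other's, the
#' covered one is removed. If they partially overlap and the non-overlapped
#' 'M' length of one version is at most `policy$overlap_residual` bp, that
#' version is removed. Placements on different contigs, or with no overlap,
#' both survive. When both versions qualify for removal the 'a' version is
#' kept (deterministic tie-break).
#'
#' @param a_hit,b_hit Single-row placements of the two versions of one read.
#' @param policy [repeat_policy()].
#' @param lengths Named contig lengths.
#' @return List: `keep` (tibble of surviving rows) and `removed_tag`
#'   (`"a"`, `"b"` or `NA`), plus `cross_locus` flag.
#' @export
resolve_version_overlap <- function(a_hit, b_hit, policy = repeat_policy(),
                                    lengths = NULL) {
  if (is.null(lengths)) {
    lengths <- setNames(pmax(a_hit$ref_end, b_hit$ref_end),
                        a_hit$contig)
  }
  if (a_hit$contig != b_hit$contig) {
    return(list(keep = dplyr::bind_rows(a_hit, b_hit), removed_tag = NA_character_,
                cross_locus = TRUE))
  }
  A <- placement_m_ir(a_hit, lengths)
  B <- placement_m_ir(b_hit, lengths)
  inter_w <- sum(IRanges::width(IRanges::intersect(A, B)))
  resid_a <- sum(IRanges::width(IRanges::setdiff(A, B)))
  resid_b <- sum(IRanges::width(IRanges::setdiff(B, A)))
  if (inter_w == 0) {
    return(list(keep = dplyr::bind_rows(a_hit, b_hit), removed_tag = NA_character_,
                cross_locus = TRUE))
  }
  if (resid_a == 0 && resid_b == 0) {
    # identical coverage: the two phases map the same segment, so the one
    # whose conversion model fits worse (lower score) is the covered duplicate
    if (b_hit$score > a_hit$score) {
      return(list(keep = b_hit, removed_tag = "a", cross_locus = FALSE))
    }
    return(list(keep = a_hit, removed_tag = "b", cross_locus = FALSE))
  }
  if (resid_b == 0) {          # b totally covered by a
    return(list(keep = a_hit, removed_tag = "b", cross_locus = FALSE))
  }
  if (resid_a == 0) {          # a totally covered by b
    return(list(keep = b_hit, removed_tag = "a", cross_locus = FALSE))
  }
  if (resid_b <= policy$overlap_residual) {
    return(list(keep = a_hit, removed_tag = "b", cross_locus = FALSE))
  }
  if (resid_a <= policy$overlap_residual) {
    return(list(keep = b_hit, removed_tag = "a", cross_locus = FALSE))
  }
  list(keep = dplyr::bind_rows(a_hit, b_hit), removed_tag = NA_character_,
       cross_locus = FALSE)
}

# ---- orchestration of steps 2-3 for a batch of candidates -------------------

# Applies repeat filtering, per-tag multi-mapping resolution and a/b overlap
# resolution. Returns survivors, audit rows, and per-entity score gaps.
apply_filters <- function(cands, repeats, policy, lengths) {
  audit <- list()
  if (nrow(cands) == 0) {
    return(list(survivors = empty_placements(), audit = tibble::tibble(),
                any_filtered = character(0)))
  }
  marked <- mark_repeats(cands, repeats, policy, lengths)
  marked <- filter_repeat_hit(marked, policy)
  removed2 <- marked[!marked$keep, , drop = FALSE]
  if (nrow(removed2) > 0) {
    audit[[length(audit) + 1]] <- tibble::tibble(
      read_id = removed2$read_id, tag = removed2$tag, stage = "repeat-filter",
      fate = "removed", reason = removed2$reason,
      n_classes = removed2$n_classes, unmarked_m = removed2$unmarked_m)
  }
  kept <- marked[marked$keep, , drop = FALSE]

  # per-tag multimapping resolution + score gap vs alternative loci
  survivors <- empty_placements()
  if (nrow(kept) > 0) {
    ranked <- kept |>
      dplyr::mutate(.sord = match(.data$strand, c("W", "C"))) |>
      dplyr::group_by(.data$read_id, .data$tag) |>
      dplyr::arrange(.data$repeat_overlap_bp, .data$contig, .data$ref_start,
                     .data$.sord, .by_group = TRUE) |>
      dplyr::mutate(.rank = dplyr::row_number()) |>
      dplyr::ungroup()
    dropped <- ranked[ranked$.rank > 1L, , drop = FALSE]
    if (nrow(dropped) > 0) {
      audit[[length(audit) + 1]] <- tibble::tibble(
        read_id = dropped$read_id, tag = dropped$tag, stage = "multimap",
        fate = "removed", reason = "longer-repeat-overlap",
        n_classes = dropped$n_classes, unmarked_m = dropped$unmarked_m)
    }
    chosen <- ranked[ranked$.rank == 1L, , drop = FALSE]
    best_other <- ranked |>
      dplyr::inner_join(
        dplyr::select(chosen, "read_id", "tag", c_contig = "contig",
                      c_start = "ref_start", c_end = "ref_end"),
        by = c("read_id", "tag")) |>
      dplyr::filter(!(.data$contig == .data$c_contig &
                        .data$ref_start < .data$c_end &
                        .data$c_start < .data$ref_end)) |>
      dplyr::group_by(.data$read_id, .data$tag) |>
      dplyr::summarise(.best_other = max(c(-Inf, .data$score)), .groups = "drop")
    survivors <- chosen |>
      dplyr::left_join(best_other, by = c("read_id", "tag")) |>
      dplyr::mutate(score_gap = ifelse(is.na(.data$.best_other), Inf,
                                       .data$score - .data$.best_other)) |>
      dplyr::select(-".sord", -".rank", -".best_other")
  }

  # a/b version overlap resolution
  if (nrow(survivors) > 0) {
    survivors$.row <- seq_len(nrow(survivors))
    paired_ids <- names(which(table(survivors$read_id) == 2L))
    drop_rows <- integer(0)
    if (length(paired_ids) > 0) {
      a <- survivors[survivors$tag == "a" & survivors$read_id %in% paired_ids, ]
      b <- survivors[survivors$tag == "b" & survivors$read_id %in% paired_ids, ]
      a <- a[match(paired_ids, a$read_id), ]
      b <- b[match(paired_ids, b$read_id), ]
      gapfree <- grepl("^[0-9]+M$", a$cigar) & grepl("^[0-9]+M$", b$cigar)

      # fast path: contiguous alignments resolved arithmetically
      same <- a$contig == b$contig
      inter <- ifelse(same,
                      pmax(0L, pmin(a$ref_end, b$ref_end) - pmax(a$ref_start, b$ref_start)),
                      0L)
      resid_a <- (a$ref_end - a$ref_start) - inter
      resid_b <- (b$ref_end - b$ref_start) - inter
      rm_tag <- rep(NA_character_, length(paired_ids))
      cross <- rep(FALSE, length(paired_ids))
      for (i in seq_along(paired_ids)) {
        if (gapfree[i]) {
          if (!same[i] || inter[i] == 0L) { cross[i] <- TRUE; next }
          if (resid_a[i] == 0L && resid_b[i] == 0L) {
            rm_tag[i] <- if (b$score[i] > a$score[i]) "a" else "b"
          } else if (resid_b[i] == 0L) rm_tag[i] <- "b"
          else if (resid_a[i] == 0L) rm_tag[i] <- "a"
          else if (resid_b[i] <= policy$overlap_residual) rm_tag[i] <- "b"
          else if (resid_a[i] <= policy$overlap_residual) rm_tag[i] <- "a"
        } else {
          res <- resolve_version_overlap(a[i, ], b[i, ], policy, lengths)
          rm_tag[i] <- res$removed_tag
          cross[i] <- res$cross_locus
        }
      }
      rm_a <- which(rm_tag == "a"); rm_b <- which(rm_tag == "b")
      drop_rows <- c(a$.row[rm_a], b$.row[rm_b])
      if (length(drop_rows) > 0) {
        rem <- dplyr::bind_rows(a[rm_a, ], b[rm_b, ])
        audit[[length(audit) + 1]] <- tibble::tibble(
          read_id = rem$read_id, tag = rem$tag, stage = "version-overlap",
          fate = "removed", reason = "covered-by-other-version",
          n_classes = rem$n_classes, unmarked_m = rem$unmarked_m)
      }
      if (any(cross)) {
        audit[[length(audit) + 1]] <- tibble::tibble(
          read_id = paired_ids[cross], tag = "a+b", stage = "version-overlap",
          fate = "kept", reason = "cross-locus-pair",
          n_classes = NA_integer_, unmarked_m = NA_integer_)
      }
    }
    if (length(drop_rows) > 0) survivors <- survivors[-drop_rows, , drop = FALSE]
    survivors$.row <- NULL
    survivors <- dplyr::arrange(survivors, .data$read_id, .data$tag)
  }

  audit_tbl <- if (length(audit)) dplyr::bind_rows(audit) else
    tibble::tibble(read_id = character(), tag = character(), stage = character(),
                   fate = character(), reason = character(),
                   n_classes = integer(), unmarked_m = integer())
  list(survivors = survivors, audit = audit_tbl,
       any_filtered = unique(removed2$read_id))
}

# midpoint split of unmapped reads; fragments below min_len are discarded
split_reads <- function(reads, min_len, round) {
  eligible <- reads[nchar(reads$bases) > min_len, , drop = FALSE]
  if (nrow(eligible) == 0) {
    return(tibble::tibble(id = character(), bases = character(),
                          quality = list(), root = character()))
  }
  len <- nchar(eligible$bases)
  mid <- len %/% 2L
  root <- if ("root" %in% names(eligible)) eligible$root else eligible$id
  frag <- dplyr::bind_rows(
    tibble::tibble(id = paste0(eligible$id, ":s", round, "f1"),
                   bases = substr(eligible$bases, 1L, mid),
                   root = root),
    tibble::tibble(id = paste0(eligible$id, ":s", round, "f2"),
                   bases = substr(eligible$bases, mid + 1L, len),
                   root = root))
  frag <- frag[nchar(frag$bases) >= min_len, , drop = FALSE]
  frag$quality <- vector("list", nrow(frag))
  frag[order(match(frag$root, reads$id), frag$id), ]
}

#' Map and filter reads end to end (pipeline steps 1-4)
#'
#' Runs dual-phase mapping, repeat filtering, multi-mapping and a/b overlap
#' resolution, then splits still-unmapped reads longer than
#' `policy$remap_min_len` bp at their midpoint and sends the fragments back
#' through the same steps (at most 2 split rounds).
#'
#' @param reads Reads tibble (`id`, `bases`).
#' @param cref [build_converted_reference()] output.
#' @param repeats Repeat intervals tibble, or `NULL`.
#' @param params [align_params()].
#' @param policy [repeat_policy()].
#' @param use_seeds Passed to [map_reads()].
#' @param cands1 Optional precomputed round-1 candidate placements (as
#'   produced by [map_reads()] on the tagged reads); used by the file-based
#'   `map`/`filter` stage split.
#' @return List with `placements` (surviving placements; `parent_id` links
#'   fragments to their original read; `unique` flag set), `fates` (one row
#'   per input read: `read_id`, `fate` in unique/multi/filtered/unmapped,
#'   `reason`, `n_placements`), and `audit` (per-candidate filter decisions).
#' @export
map_filter_reads <- function(reads, cref, repeats = NULL,
                             params = align_params(), policy = repeat_policy(),
                             use_seeds = NA, cands1 = NULL) {
  lengths <- cref$lengths
  all_surv <- list(); all_audit <- list(); filtered_roots <- character(0)

  batch <- reads
  batch$root <- reads$id
  for (round in 1:3) {
    if (nrow(batch) == 0) break
    cands <- if (round == 1 && !is.null(cands1)) cands1 else
      map_reads(tag_reads(batch), cref, params, use_seeds)
    res <- apply_filters(cands, repeats, policy, lengths)
    surv <- res$survivors
    if (nrow(surv) > 0) {
      surv$parent_id <- batch$root[match(surv$read_id, batch$id)]
      surv$round <- round
      all_surv[[length(all_surv) + 1]] <- surv
    }
    if (nrow(res$audit) > 0) all_audit[[length(all_audit) + 1]] <- res$audit
    filtered_roots <- union(filtered_roots,
                            batch$root[match(res$any_filtered, batch$id)])
    unmapped <- batch[!(batch$id %in% surv$read_id), , drop = FALSE]
    if (round == 3) break
    batch <- split_reads(unmapped, policy$remap_min_len, round)
  }

  placements <- if (length(all_surv)) dplyr::bind_rows(all_surv) else {
    p <- empty_placements()
    p$score_gap <- numeric(0); p$parent_id <- character(0); p$round <- integer(0)
    p$n_classes <- integer(0); p$marked_bp <- integer(0)
    p$repeat_overlap_bp <- integer(0); p$classes <- character(0)
    p$unmarked_m <- integer(0); p$keep <- logical(0); p$reason <- character(0)
    p
  }

  # read fates
  n_place <- table(placements$parent_id)
  fates <- tibble::tibble(read_id = reads$id)
  fates$n_placements <- as.integer(n_place[fates$read_id])
  fates$n_placements[is.na(fates$n_placements)] <- 0L
  singly <- names(n_place)[n_place == 1L]
  placements$unique <- placements$parent_id %in% singly &
    placements$score_gap > params$unique_margin
  unique_ids <- placements$parent_id[placements$unique]
  fates$fate <- dplyr::case_when(
    fates$read_id %in% unique_ids ~ "unique",
    fates$n_placements >= 1L ~ "multi",
    fates$read_id %in% filtered_roots ~ "filtered",
    TRUE ~ "unmapped")
  fates$reason <- ifelse(fates$fate == "filtered", "repeat-filter", NA_character_)

  audit <- if (length(all_audit)) dplyr::bind_rows(all_audit) else
    tibble::tibble(read_id = character(), tag = character(), stage = character(),
                   fate = character(), reason = character(),
                   n_classes = integer(), unmarked_m = integer())
  list(placements = placements, fates = fates, audit = audit)
}
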