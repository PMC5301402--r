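#' Region-calling parameters
#'
#' The peak-extension rule: the `n_top` best-ranked SNPs seed regions; SNPs
#' ranked in the top `secondary_fraction` of the scan and lying within
#' `window_bp` of a seed extend it; overlapping regions merge.
#'
#' @param n_top number of seed SNPs (default 50).
#' @param secondary_fraction rank fraction for extension SNPs
#'   (default 0.005, i.e. top 0.5%).
#' @param window_bp maximum distance of an extension SNP from its seed
#'   (default 1.5 Mb).
#' @return list of class `region_params`.
#' @export
region_params <- function(n_top = 50, secondary_fraction = 0.005,
                          window_bp = 1500000) {
  stopifnot(n_top >= 1, secondary_fraction > 0, secondary_fraction <= 1,
            window_bp >= 0)
  structure(list(n_top = n_top, secondary_fraction = secondary_fraction,
                 window_bp = window_bp), class = "region_params")
}

#' Rank SNP scores
#'
#' Rank 1 is the most extreme score: the largest value for
#' `direction = "desc"` (Fst), the smallest for `direction = "asc"`
#' (p-values). Ties are broken by genome position (chromosome, then bp),
#' ascending, so ranks are a deterministic permutation. Non-finite values
#' are excluded from ranking and get `NA`.
#'
#' @param track an `assoc_track` data.frame (columns `chrom`, `pos_bp`,
#'   `value`).
#' @param direction `"desc"` or `"asc"`; when missing, inferred from the
#'   track's statistic attribute (p-value tracks ascend).
#' @return integer vector of ranks aligned to the track.
#' @export
rank_scores <- function(track, direction = NULL) {
  if (is.null(direction)) {
    stat <- attr(track, "statistic")
    direction <- if (!is.null(stat) && grepl("_p$", stat)) "asc" else "desc"
  }
  direction <- match.arg(direction, c("desc", "asc"))
  v <- track$value
  ok <- is.finite(v)
  if (!any(ok)) stop("no finite values to rank")
  key <- if (direction == "desc") -v else v
  key[!ok] <- NA
  o <- order(key, chrom_rank(track$chrom), track$chrom, track$pos_bp,
             na.last = TRUE)
  ranks <- rep(NA_integer_, length(v))
  ranks[o[seq_len(sum(ok))]] <- seq_len(sum(ok))
  ranks
}

#' Call candidate regions by the peak-extension rule
#'
#' Seeds are the `n_top` best-ranked SNPs (T1). Extension SNPs (T2) are
#' those ranked within the top `secondary_fraction` of all ranked SNPs
#' (count `ceiling(secondary_fraction * N)`). Each seed's region spans the
#' seed and every T2 SNP on the same chromosome within `window_bp` of it;
#' overlapping or book-ended regions on a chromosome are merged
#' transitively, and a merged region's peak is its best-ranked member.
#' Intervals are 1-based closed.
#'
#' @param track an `assoc_track`.
#' @param params a [region_params()] object.
#' @param direction passed to [rank_scores()].
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`,
#'   `peak_marker_id`, `peak_pos_bp`, `peak_value`, `n_members` and a
#'   list-column `members` of member marker ids.
#' @export
call_regions <- function(track, params = region_params(), direction = NULL) {
  ranks <- rank_scores(track, direction)
  n_ranked <- sum(!is.na(ranks))
  n_top <- params$n_top
  if (n_ranked < n_top) {
    warning("only ", n_ranked, " ranked markers; using all as seeds")
    n_top <- n_ranked
  }
  n_t2 <- ceiling(params$secondary_fraction * n_ranked)
  t1 <- which(!is.na(ranks) & ranks <= n_top)
  t2 <- which(!is.na(ranks) & ranks <= n_t2)

  seeds <- lapply(t1, function(s) {
    nb <- t2[track$chrom[t2] == track$chrom[s] &
             abs(track$pos_bp[t2] - track$pos_bp[s]) <= params$window_bp]
    members <- sort(unique(c(s, nb)))
    list(chrom = track$chrom[s],
         start_bp = min(track$pos_bp[members]),
         end_bp = max(track$pos_bp[members]),
         members = members)
  })

  # transitive merge of overlapping/book-ended intervals per chromosome
  chroms <- vapply(seeds, `[[`, character(1), "chrom")
  out <- list()
  for (ch in unique(chroms[order(chrom_rank(chroms), chroms)])) {
    rs <- seeds[chroms == ch]
    o <- order(vapply(rs, `[[`, numeric(1), "start_bp"),
               vapply(rs, `[[`, numeric(1), "end_bp"))
    rs <- rs[o]
    cur <- rs[[1]]
    for (r in rs[-1]) {
      if (r$start_bp <= cur$end_bp) {
        cur$end_bp <- max(cur$end_bp, r$end_bp)
        cur$members <- sort(unique(c(cur$members, r$members)))
      } else {
        out[[length(out) + 1]] <- cur
        cur <- r
      }
    }
    out[[length(out) + 1]] <- cur
  }

  res <- do.call(rbind, lapply(out, function(r) {
    peak <- r$members[which.min(ranks[r$members])]
    data.frame(chrom = r$chrom, start_bp = r$start_bp, end_bp = r$end_bp,
               peak_marker_id = track$marker_id[peak],
               peak_pos_bp = track$pos_bp[peak],
               peak_value = track$value[peak],
               n_members = length(r$members), stringsAsFactors = FALSE)
  }))
  res$members <- lapply(out, function(r) track$marker_id[r$members])
  attr(res, "statistic") <- attr(track, "statistic")
  res
}

#' Intersect two region sets into dual-support VGR
#'
#' A variable genomic region (VGR) is emitted for every connected component
#' of the overlap graph between the two per-method region sets: regions on
#' the same chromosome whose closed intervals intersect (zero-length
#' regions are points) are connected, components spanning both methods form
#' one VGR whose interval is the union span, carrying the best peak from
#' each side. Regions supported by only one method are dropped.
#'
#' @param plink_regions,emmax_regions outputs of [call_regions()] (merged,
#'   internally non-overlapping). The first carries Fst peaks (larger is
#'   better), the second p-value peaks (smaller is better).
#' @return data.frame with columns `vgr`, `chrom`, `start_bp`, `end_bp`,
#'   `plink_peak_pos`, `plink_peak_value`, `emmax_peak_pos`,
#'   `emmax_peak_value`.
#' @export
intersect_region_sets <- function(plink_regions, emmax_regions) {
  empty <- data.frame(vgr = integer(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      plink_peak_pos = numeric(), plink_peak_value = numeric(),
                      emmax_peak_pos = numeric(), emmax_peak_value = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(plink_regions) || is.null(emmax_regions) ||
      nrow(plink_regions) == 0 || nrow(emmax_regions) == 0)
    return(empty)
  na <- nrow(plink_regions)
  nb <- nrow(emmax_regions)
  # union-find over the na + nb regions
  parent <- seq_len(na + nb)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  linked <- FALSE
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (plink_regions$chrom[i] == emmax_regions$chrom[j] &&
        plink_regions$start_bp[i] <= emmax_regions$end_bp[j] &&
        emmax_regions$start_bp[j] <= plink_regions$end_bp[i]) {
      parent[find(i)] <- find(na + j)
      linked <- TRUE
    }
  }
  if (!linked) return(empty)
  comp <- vapply(seq_len(na + nb), find, integer(1))
  rows <- list()
  for (cp in unique(comp)) {
    ia <- which(comp[seq_len(na)] == cp)
    ib <- which(comp[na + seq_len(nb)] == cp)
    if (length(ia) == 0 || length(ib) == 0) next
    pa <- ia[which.max(plink_regions$peak_value[ia])]
    pb <- ib[which.min(emmax_regions$peak_value[ib])]
    rows[[length(rows) + 1]] <- data.frame(
      chrom = plink_regions$chrom[pa],
      start_bp = min(plink_regions$start_bp[ia], emmax_regions$start_bp[ib]),
      end_bp = max(plink_regions$end_bp[ia], emmax_regions$end_bp[ib]),
      plink_peak_pos = plink_regions$peak_pos_bp[pa],
      plink_peak_value = plink_regions$peak_value[pa],
      emmax_peak_pos = emmax_regions$peak_pos_bp[pb],
      emmax_peak_value = emmax_regions$peak_value[pb],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res <- res[order(chrom_rank(res$chrom), res$chrom, res$start_bp), ,
             drop = FALSE]
  res <- cbind(vgr = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Score VGR recovery against planted truth
#'
#' A planted interval counts as recovered when some VGR overlaps it after
#' widening both by `slack_bp`; a VGR overlapping no (widened) planted
#' interval is a false positive.
#'
#' @param vgrs output of [intersect_region_sets()] (or any data.frame with
#'   `chrom`, `start_bp`, `end_bp`).
#' @param truth a `sim_truth` object (or a data.frame of planted intervals
#'   with `chrom`, `start_bp`, `end_bp`).
#' @param slack_bp allowed distance between a VGR and a planted interval.
#' @return list with `sensitivity` and `false_positive_count`.
#' @export
recovery_score <- function(vgrs, truth, slack_bp = 0) {
  planted <- if (inherits(truth, "sim_truth")) truth$regions else truth
  if (is.null(planted) || nrow(planted) == 0)
    return(list(sensitivity = NA_real_,
                false_positive_count = if (is.null(vgrs)) 0L else nrow(vgrs)))
  if (is.null(vgrs) || nrow(vgrs) == 0)
    return(list(sensitivity = 0, false_positive_count = 0L))
  hit <- matrix(FALSE, nrow(vgrs), nrow(planted))
  for (i in seq_len(nrow(vgrs))) for (j in seq_len(nrow(planted))) {
    hit[i, j] <- vgrs$chrom[i] == planted$chrom[j] &&
      vgrs$start_bp[i] <= planted$end_bp[j] + slack_bp &&
      planted$start_bp[j] <= vgrs$end_bp[i] + slack_bp
  }
  list(sensitivity = mean(colSums(hit) > 0),
       false_positive_count = sum(rowSums(hit) == 0))
}

#' Write regions as BED (0-based half-open)
#'
#' @param regions data.frame with `chrom`, `start_bp`, `end_bp` (1-based
#'   closed) and optionally a name column.
#' @param path output path.
#' @param names optional character vector of interval names.
#' @export
write_regions_bed <- function(regions, path, names = NULL) {
  if (is.null(names))
    names <- if ("peak_marker_id" %in% base::names(regions))
      regions$peak_marker_id else paste0("region_", seq_len(nrow(regions)))
  bed <- data.frame(regions$chrom, regions$start_bp - 1, regions$end_bp,
                    names)
  utils::write.table(bed, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
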