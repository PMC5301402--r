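#' Read candidate-gene intervals
#'
#' Accepts BED (0-based half-open: chrom, start, end, name[, source_tag])
#' or a 4+-column TSV in 1-based closed coordinates (chrom, start_bp,
#' end_bp, name[, source_tag]). Intervals are normalized to the package's
#' internal 1-based closed convention and sorted by (chromosome, start).
#'
#' @param path input file.
#' @param format `"bed"` or `"tsv"`.
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`, `name`,
#'   `source_tag`.
#' @export
read_gene_intervals <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), name = character(),
                      source_tag = character(), stringsAsFactors = FALSE))
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) < 4)
      stop("malformed interval line ", i, ": need at least 4 columns")
    start <- suppressWarnings(as.numeric(tok[2]))
    end <- suppressWarnings(as.numeric(tok[3]))
    if (is.na(start) || is.na(end))
      stop("malformed interval line ", i, ": non-numeric coordinates")
    if (format == "bed") {
      if (end <= start)
        stop("malformed interval line ", i, ": BED end must exceed start")
      start <- start + 1          # to 1-based closed
    } else if (end < start) {
      stop("malformed interval line ", i, ": end before start")
    }
    data.frame(chrom = tok[1], start_bp = start, end_bp = end,
               name = tok[4],
               source_tag = if (length(tok) >= 5) tok[5] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(chrom_rank(out$chrom), out$chrom, out$start_bp), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate VGR with candidate genes
#'
#' For every VGR x gene pair on the same chromosome, emits a hit when the
#' intervals intersect (`relation = "inside"` if the gene lies entirely
#' within the VGR, else `"overlapping"`, both with distance 0) or when the
#' gap between the closed intervals is at most `flank_bp`
#' (`relation = "proximal"`, distance = the gap in bp). With `flank_bp = 0`
#' this reduces to pure interval intersection.
#'
#' @param vgrs data.frame with `vgr` (index), `chrom`, `start_bp`, `end_bp`.
#' @param genes data.frame from [read_gene_intervals()].
#' @param flank_bp maximum gap for a proximal hit (default 3 Mb).
#' @return data.frame with columns `vgr`, `gene`, `relation`, `distance_bp`,
#'   `source_tag`.
#' @export
annotate_regions <- function(vgrs, genes, flank_bp = 3000000) {
  rows <- list()
  if (!"vgr" %in% names(vgrs)) vgrs$vgr <- seq_len(nrow(vgrs))
  for (i in seq_len(nrow(vgrs))) for (j in seq_len(nrow(genes))) {
    if (vgrs$chrom[i] != genes$chrom[j]) next
    gap <- max(0, genes$start_bp[j] - vgrs$end_bp[i],
               vgrs$start_bp[i] - genes$end_bp[j])
    if (gap == 0) {
      relation <- if (genes$start_bp[j] >= vgrs$start_bp[i] &&
                      genes$end_bp[j] <= vgrs$end_bp[i])
        "inside" else "overlapping"
    } else if (gap <= flank_bp) {
      relation <- "proximal"
    } else next
    rows[[length(rows) + 1]] <- data.frame(
      vgr = vgrs$vgr[i], gene = genes$name[j], relation = relation,
      distance_bp = gap, source_tag = genes$source_tag[j],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(vgr = integer(), gene = character(),
                      relation = character(), distance_bp = numeric(),
                      source_tag = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
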