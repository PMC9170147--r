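# Genetic maps: marker coordinates in bp and cM per chromosome.
# A map is a data.frame (class "gc_map") with columns
#   marker (character), chrom (integer), pos_bp (integer), pos_cM (numeric),
# sorted by (chrom, pos_bp), strictly increasing bp and non-decreasing cM
# within each chromosome.

#' Build a genetic map
#'
#' Creates a marker map for `n_chrom` chromosomes.  With
#' `placement = "uniform"` (default) marker *i* of *m* on a chromosome of
#' physical length *L* bp sits at `round(i * L / m)` bp; with
#' `placement = "random"` positions are drawn uniformly without replacement
#' from `1:L` and sorted.  Genetic positions are proportional to physical
#' positions (`pos_cM = pos_bp * chrom_length_cM / chrom_length_bp`), i.e.
#' a uniform recombination rate (default 1 cM/Mb when the lengths are left
#' at 100 cM per 100 Mb).  Lengths may be scalars (recycled) or per-
#' chromosome vectors.
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome (scalar or vector).
#' @param chrom_length_cM genetic length per chromosome in cM.
#' @param chrom_length_bp physical length per chromosome in bp.
#' @param placement `"uniform"` or `"random"`.
#' @param seed integer seed (only used for random placement).
#' @return a `gc_map` data.frame.
#' @examples
#' map <- make_genetic_map(1, 100, 100, 100e6)
#' tail(map, 1)$pos_cM  # 100
#' @export
make_genetic_map <- function(n_chrom, markers_per_chrom, chrom_length_cM = 100,
                             chrom_length_bp = 100e6,
                             placement = c("uniform", "random"), seed = NULL) {
  placement <- match.arg(placement)
  if (n_chrom < 1) stop_gc("n_chrom must be positive")
  m <- rep_len(as.integer(markers_per_chrom), n_chrom)
  if (any(m < 1)) stop_gc("markers_per_chrom must be positive")
  len_cM <- rep_len(chrom_length_cM, n_chrom)
  len_bp <- rep_len(chrom_length_bp, n_chrom)
  if (any(len_cM < 0) || any(len_bp <= 0)) stop_gc("chromosome lengths must be positive")
  with_seed(seed, {
    pieces <- lapply(seq_len(n_chrom), function(ch) {
      bp <- switch(placement,
        uniform = round(seq_len(m[ch]) * len_bp[ch] / m[ch]),
        random  = sort(sample.int(len_bp[ch], m[ch]))
      )
      data.frame(
        marker = sprintf("chr%d_%d", ch, seq_len(m[ch])),
        chrom = ch,
        pos_bp = as.numeric(bp),
        pos_cM = bp * len_cM[ch] / len_bp[ch],
        stringsAsFactors = FALSE
      )
    })
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  class(map) <- c("gc_map", "data.frame")
  validate_map(map)
  map
}

validate_map <- function(map) {
  stopifnot(all(c("marker", "chrom", "pos_bp", "pos_cM") %in% names(map)))
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    if (any(diff(sub$pos_bp) <= 0)) stop_gc("bp positions must be strictly increasing within chromosome ", ch)
    if (any(diff(sub$pos_cM) < 0)) stop_gc("cM positions must be non-decreasing within chromosome ", ch)
  }
  if (anyDuplicated(map$marker)) stop_gc("duplicated marker ids")
  invisible(map)
}

n_markers <- function(map) nrow(map)

# per-chromosome row index list, in map order
chrom_index <- function(map) split(seq_len(nrow(map)), map$chrom)

#' Write / read a genetic map as 4-column TSV
#'
#' Columns: marker, chrom, pos_bp, pos_cM.
#' @param map a `gc_map`.
#' @param path file path.
#' @return `read_map` returns a `gc_map`.
#' @export
write_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(map) <- c("gc_map", "data.frame")
  validate_map(map)
  map
}
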