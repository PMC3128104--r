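#' Read exon intervals from a BED file
#'
#' Reads the first three (optionally four) columns of a BED file.
#' BED coordinates are 0-based half-open; they are converted to the
#' 1-based inclusive convention used for SNP positions.
#'
#' @param path Path to a BED file (no header).
#' @return Data frame with columns `chrom`, `start`, `end`, `gene_id`
#'   (1-based inclusive coordinates).
#' @export
read_exons_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("BED file needs at least 3 columns")
  data.frame(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]]),
    gene_id = if (ncol(raw) >= 4) as.character(raw[[4]]) else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Read exon intervals from a refGene-style table
#'
#' Parses the UCSC refGene format, where each transcript row carries
#' comma-separated `exonStarts` and `exonEnds` lists in 0-based
#' half-open coordinates. Each exon becomes one interval, converted to
#' 1-based inclusive coordinates.
#'
#' @param path Path to a tab-delimited refGene table with a header
#'   containing at least `chrom`, `exonStarts`, `exonEnds` and
#'   optionally `name2` (gene symbol).
#' @return Data frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_exons_refgene <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "exonStarts", "exonEnds")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("refGene table missing column(s): ", paste(miss, collapse = ", "))
  starts <- strsplit(raw$exonStarts, ",", fixed = TRUE)
  ends <- strsplit(raw$exonEnds, ",", fixed = TRUE)
  n_ex <- lengths(starts)
  data.frame(
    chrom = rep(raw$chrom, n_ex),
    start = as.integer(unlist(starts)) + 1L,
    end = as.integer(unlist(ends)),
    gene_id = if ("name2" %in% names(raw))
      rep(raw$name2, n_ex) else NA_character_,
    stringsAsFactors = FALSE
  )
}

# merge overlapping/adjacent intervals within one chromosome;
# x is a data frame with start/end sorted by start
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  n <- length(start)
  if (n <= 1) return(list(start = start, end = end))
  ms <- numeric(n); me <- numeric(n)
  k <- 1L
  ms[1] <- start[1]; me[1] <- end[1]
  for (i in 2:n) {
    if (start[i] <= me[k] + 1) {
      if (end[i] > me[k]) me[k] <- end[i]
    } else {
      k <- k + 1L
      ms[k] <- start[i]; me[k] <- end[i]
    }
  }
  list(start = ms[seq_len(k)], end = me[seq_len(k)])
}

#' Distance from each SNP to the nearest exon
#'
#' For each SNP, finds the minimal gap in basepairs to any exon on the
#' same chromosome within `window_bp`. A SNP lying inside an exon has
#' distance 0. Distance to an exon downstream of the SNP is
#' `start - pos`; upstream, `pos - end`. SNPs with no exon within the
#' window (or on a chromosome absent from the exon table) get `NA`
#' distance and `FALSE` for every indicator. Overlapping exons are
#' merged before the search.
#'
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based).
#' @param exons Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. from [read_exons_bed()].
#' @param window_bp Search window in basepairs (default 1e6).
#' @param thresholds Integer vector of near-exon distance cutoffs in
#'   basepairs; one logical column `near_<d>` is added per cutoff
#'   (default `c(2000, 25000)`, the two headline strata).
#' @return Data frame: `snp_id`, `chrom`, `pos`, `exon_distance`
#'   (integer, `NA` if none within window), and one `near_<d>` column
#'   per threshold with `near_<d> = (exon_distance <= d)`.
#' @export
nearest_exon_distance <- function(snps, exons, window_bp = 1e6,
                                  thresholds = c(2000, 25000)) {
  stopifnot(window_bp > 0, all(thresholds > 0))
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)))
  stopifnot(all(c("chrom", "start", "end") %in% names(exons)))
  if (any(exons$start > exons$end)) stop("exon interval with start > end")
  dist <- rep(NA_real_, nrow(snps))
  missing_chrom <- setdiff(unique(snps$chrom), unique(exons$chrom))
  if (length(missing_chrom) > 0)
    warning("no exons on chromosome(s): ",
            paste(missing_chrom, collapse = ", "))
  for (chr in intersect(unique(snps$chrom), unique(exons$chrom))) {
    idx <- which(snps$chrom == chr)
    e <- exons[exons$chrom == chr, , drop = FALSE]
    m <- merge_intervals(e$start, e$end)
    pos <- snps$pos[idx]
    # i = index of last merged exon with start <= pos
    i <- findInterval(pos, m$start)
    d_inside_or_left <- ifelse(i >= 1,
                               pmax(pos - m$end[pmax(i, 1)], 0), Inf)
    has_right <- i < length(m$start)
    d_right <- ifelse(has_right,
                      m$start[pmin(i + 1, length(m$start))] - pos, Inf)
    d <- pmin(d_inside_or_left, d_right)
    d[d > window_bp] <- NA
    dist[idx] <- d
  }
  out <- data.frame(snp_id = snps$snp_id, chrom = snps$chrom,
                    pos = snps$pos, exon_distance = as.integer(dist),
                    stringsAsFactors = FALSE)
  for (d in sort(thresholds)) {
    out[[paste0("near_", d)]] <- !is.na(out$exon_distance) &
      out$exon_distance <= d
  }
  rownames(out) <- NULL
  out
}

#' Sweep near-exon thresholds through the interaction model
#'
#' For each distance cutoff in `grid`, recomputes the near-exon
#' indicator and fits the power-by-proximity interaction model
#' (Model II), returning the interaction term's estimate and P-value.
#' Used to profile at which distance from exons the enrichment of
#' replication is strongest.
#'
#' @param records Power-record table from [power_records()] that
#'   includes `exon_distance`.
#' @param grid Ascending integer vector of distance cutoffs (bp).
#' @return Data frame with columns `threshold_bp`, `estimate`,
#'   `p_value`, `neg_log10_p` for the power-by-near-exon interaction.
#' @export
distance_sweep <- function(records, grid) {
  stopifnot(all(diff(grid) > 0), all(grid > 0),
            "exon_distance" %in% names(records))
  res <- lapply(grid, function(d) {
    r <- records
    r[[paste0("near_", d)]] <- !is.na(r$exon_distance) &
      r$exon_distance <= d
    fit <- fit_model(r, "II", near_exon_threshold_bp = d)
    co <- fit$coefficients["power:near_exon", ]
    data.frame(threshold_bp = d, estimate = co$estimate,
               p_value = co$p_value,
               neg_log10_p = -log10(co$p_value))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
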