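#' Interpolate a SNP's genetic position from microsatellite anchors
#'
#' SNPs between two anchors get the linear interpolation of the anchors'
#' genetic positions by physical position. Beyond the first or last anchor
#' of a chromosome only one anchor is available, so the conventional
#' 1 cM per 1e6 bp conversion extends the map outward.
#'
#' @param pm_snp Physical position(s) in bp.
#' @param anchors `data.frame` with columns `gm` (cM) and `pm` (bp) for one
#'   chromosome, strictly increasing in `pm` and non-decreasing in `gm`.
#' @return Genetic position(s) in cM.
#' @examples
#' anchors <- data.frame(name = c("a", "b"), gm = c(0, 4),
#'                       pm = c(1e6, 3e6))
#' interpolate_genetic_position(2e6, anchors)  # 2 cM
#' @export
interpolate_genetic_position <- function(pm_snp, anchors) {
  if (!is.data.frame(anchors) || nrow(anchors) == 0)
    stop("at least one anchor is required")
  if (is.unsorted(anchors$pm, strictly = TRUE) || is.unsorted(anchors$gm))
    stop("anchors must be strictly increasing in pm and non-decreasing in gm")
  pm <- anchors$pm
  gm <- anchors$gm
  vapply(pm_snp, function(x) {
    if (x <= pm[1]) return(gm[1] - (pm[1] - x) / 1e6)
    if (x >= pm[length(pm)]) return(gm[length(pm)] + (x - pm[length(pm)]) / 1e6)
    i <- findInterval(x, pm)
    gm[i] + (x - pm[i]) / (pm[i + 1] - pm[i]) * (gm[i + 1] - gm[i])
  }, numeric(1))
}

#' Marker cleaning for a common microsatellite/SNP map
#'
#' Applies, in order: (1) drop microsatellites lacking a physical position;
#' (2) drop SNPs with minor allele frequency at or below `maf_cutoff`;
#' (3) drop SNPs within `flank_bp` of any retained microsatellite on the
#' same chromosome (to avoid LD between the anchor and the tested SNP).
#' Each marker is counted under the first rule it violates.
#'
#' @param markers `data.frame` with columns `name`, `chr`, `pm`, `kind`
#'   (`"microsatellite"` or `"snp"`), `maf` (may be `NA`), and optionally
#'   `gm`.
#' @param maf_cutoff MAF exclusion bound, inclusive (default 0.05).
#' @param flank_bp Exclusion window around each retained microsatellite,
#'   inclusive (default 1000).
#' @return The retained markers, with attribute `"report"`: counts per
#'   exclusion reason.
#' @export
clean_markers <- function(markers, maf_cutoff = 0.05, flank_bp = 1000) {
  if (nrow(markers) == 0) {
    attr(markers, "report") <- data.frame(
      reason = c("missing_position", "low_maf", "near_microsatellite"),
      n = c(0L, 0L, 0L), stringsAsFactors = FALSE)
    return(markers)
  }
  is_ms <- markers$kind == "microsatellite"
  drop_pos <- is_ms & is.na(markers$pm)
  drop_maf <- !drop_pos & !is_ms & !is.na(markers$maf) &
    markers$maf <= maf_cutoff
  kept_ms <- markers[is_ms & !drop_pos, , drop = FALSE]
  near_ms <- vapply(seq_len(nrow(markers)), function(i) {
    if (is_ms[i] || drop_pos[i] || drop_maf[i] || is.na(markers$pm[i]))
      return(FALSE)
    ms <- kept_ms[kept_ms$chr == markers$chr[i], , drop = FALSE]
    nrow(ms) > 0 && any(abs(ms$pm - markers$pm[i]) <= flank_bp)
  }, logical(1))
  keep <- !(drop_pos | drop_maf | near_ms)
  out <- markers[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- data.frame(
    reason = c("missing_position", "low_maf", "near_microsatellite"),
    n = c(sum(drop_pos), sum(drop_maf), sum(near_ms)),
    stringsAsFactors = FALSE)
  out
}

#' Build the common genetic map of microsatellites and SNPs
#'
#' Assigns every SNP a genetic position by interpolating against the
#' microsatellite anchors of its chromosome, then merges both marker kinds
#' into one map sorted by chromosome, genetic and physical position.
#'
#' @param microsatellites `data.frame` with `name`, `chr`, `gm`, `pm`
#'   (anchors; cleaned).
#' @param snps `data.frame` with `name`, `chr`, `pm` (cleaned).
#' @return A `data.frame` `name`, `chr`, `kind`, `gm`, `pm`, sorted per
#'   chromosome, monotone in `pm` within chromosome.
#' @export
build_common_map <- function(microsatellites, snps) {
  missing_anchor <- setdiff(unique(snps$chr), unique(microsatellites$chr))
  if (length(missing_anchor))
    stop("chromosome(s) without microsatellite anchors: ",
         paste(missing_anchor, collapse = ", "))
  snp_rows <- lapply(unique(snps$chr), function(ch) {
    s <- snps[snps$chr == ch, , drop = FALSE]
    a <- microsatellites[microsatellites$chr == ch, , drop = FALSE]
    a <- a[order(a$pm), , drop = FALSE]
    data.frame(name = s$name, chr = ch, kind = "snp",
               gm = interpolate_genetic_position(s$pm, a), pm = s$pm,
               stringsAsFactors = FALSE)
  })
  ms_rows <- data.frame(name = microsatellites$name, chr = microsatellites$chr,
                        kind = "microsatellite", gm = microsatellites$gm,
                        pm = microsatellites$pm, stringsAsFactors = FALSE)
  out <- rbind(ms_rows, do.call(rbind, snp_rows))
  out <- out[order(out$chr, out$gm, out$pm), , drop = FALSE]
  rownames(out) <- NULL
  out
}
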