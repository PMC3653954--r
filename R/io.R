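#' Read a LINKAGE/MERLIN-style pedigree file
#'
#' The ped file is whitespace-delimited with five leading columns (family,
#' individual, father, mother, sex), then one affection column if the
#' companion dat file declares an `A` trait, then two allele columns per
#' `M` marker in dat order. `0` is the missing code for parents and
#' alleles; affection follows the LINKAGE convention (`0`/`-9` unknown,
#' `1` unaffected, `2` affected).
#'
#' @param ped_path Path to the ped file.
#' @param dat_path Path to the companion dat file (lines `A <name>` /
#'   `M <name>`).
#' @return A `data.frame` with columns `fid`, `iid`, `father`, `mother`,
#'   `sex`, `affection`, then one character column per marker holding
#'   genotypes as `"a/b"` strings (`NA` = missing). Marker names are in
#'   attribute `"markers"`.
#' @export
read_pedfile <- function(ped_path, dat_path) {
  dat <- read_datfile(dat_path)
  markers <- dat$name[dat$type == "M"]
  has_aff <- any(dat$type == "A")
  expected <- 5L + as.integer(has_aff) + 2L * length(markers)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != expected)
  if (length(bad))
    stop("ped line ", bad[1], ": expected ", expected, " fields, found ",
         length(fields[[bad[1]]]))
  m <- do.call(rbind, fields)
  ped <- data.frame(fid = m[, 1], iid = m[, 2], father = m[, 3],
                    mother = m[, 4], sex = as.integer(m[, 5]),
                    affection = if (has_aff) as.integer(m[, 6]) else
                      rep(NA_integer_, nrow(m)),
                    stringsAsFactors = FALSE)
  dup <- duplicated(paste(ped$fid, ped$iid))
  if (any(dup))
    stop("ped line ", which(dup)[1], ": duplicate individual id ",
         ped$iid[which(dup)[1]], " in family ", ped$fid[which(dup)[1]])
  off <- 5L + as.integer(has_aff)
  for (j in seq_along(markers)) {
    a1 <- m[, off + 2L * j - 1L]
    a2 <- m[, off + 2L * j]
    g <- paste0(a1, "/", a2)
    g[a1 == "0" | a2 == "0"] <- NA_character_
    ped[[markers[j]]] <- g
  }
  attr(ped, "markers") <- markers
  ped
}

read_datfile <- function(dat_path) {
  lines <- readLines(dat_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(type = character(0), name = character(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) stop("dat line ", bad[1], ": expected '<type> <name>'")
  m <- do.call(rbind, fields)
  if (!all(m[, 1] %in% c("A", "M")))
    stop("dat file: unsupported column type ",
         paste(setdiff(m[, 1], c("A", "M")), collapse = ", "))
  data.frame(type = m[, 1], name = m[, 2], stringsAsFactors = FALSE)
}

#' Write a pedigree to LINKAGE/MERLIN-style ped + dat files
#'
#' Inverse of [read_pedfile()]: deterministic column order, missing
#' genotypes written as `0 0`, unknown affection as `0`.
#'
#' @param ped Pedigree `data.frame` as returned by [read_pedfile()].
#' @param ped_path,dat_path Output paths.
#' @param markers Marker column names, in output order (default: the
#'   `"markers"` attribute of `ped`).
#' @export
write_pedfile <- function(ped, ped_path, dat_path,
                          markers = attr(ped, "markers")) {
  if (is.null(markers)) markers <- character(0)
  key <- paste(ped$fid, ped$iid)
  known <- (ped$father == "0" | paste(ped$fid, ped$father) %in% key) &
    (ped$mother == "0" | paste(ped$fid, ped$mother) %in% key)
  if (any(!known))
    stop("unresolvable parent reference for individual ",
         ped$iid[which(!known)[1]])
  dat <- c("A affection", paste("M", markers))
  writeLines(dat, dat_path)
  aff <- ped$affection
  aff[is.na(aff)] <- 0L
  cols <- list(ped$fid, ped$iid, ped$father, ped$mother, ped$sex, aff)
  for (mk in markers) {
    g <- ped[[mk]]
    g[is.na(g)] <- "0/0"
    al <- do.call(rbind, strsplit(g, "/", fixed = TRUE))
    cols <- c(cols, list(al[, 1], al[, 2]))
  }
  writeLines(do.call(paste, cols), ped_path)
  invisible(c(ped = ped_path, dat = dat_path))
}

#' Read / write a 4-column genetic map file
#'
#' Whitespace-delimited columns: chromosome, marker name, genetic position
#' (cM), physical position (bp); no header.
#'
#' @param path File path.
#' @return `data.frame` with columns `chr`, `name`, `gm`, `pm`.
#' @export
read_mapfile <- function(path) {
  m <- utils::read.table(path, header = FALSE, col.names =
                           c("chr", "name", "gm", "pm"),
                         stringsAsFactors = FALSE)
  m
}

#' @rdname read_mapfile
#' @param map `data.frame` with columns `chr`, `name`, `gm`, `pm`.
#' @export
write_mapfile <- function(map, path) {
  utils::write.table(map[, c("chr", "name", "gm", "pm")], path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-individual, per-marker dosage table
#'
#' Tab-separated with header `individual  marker  p11  p12  p22`. Rows
#' whose probabilities sum within `0.01` of 1 (covering probabilities
#' printed at two decimals, e.g. `0.33 0.33 0.33`) are renormalized to sum
#' exactly 1; rows further off are rejected and reported, never silently
#' rescaled.
#'
#' @param path File path.
#' @return A `data.frame` of accepted rows; attribute `"rejected"` holds
#'   the rejected rows (with a `reason` column).
#' @export
read_dosage_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("individual", "marker", "p11", "p12", "p22")
  if (!all(need %in% names(d)))
    stop("dosage table must have columns: ", paste(need, collapse = ", "))
  s <- d$p11 + d$p12 + d$p22
  ok <- abs(s - 1) <= 0.01 + 1e-9 & d$p11 >= 0 & d$p12 >= 0 & d$p22 >= 0
  rejected <- d[!ok, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "probabilities do not sum to 1"
  d <- d[ok, , drop = FALSE]
  s <- s[ok]
  d$p11 <- d$p11 / s; d$p12 <- d$p12 / s; d$p22 <- d$p22 / s
  rownames(d) <- NULL
  attr(d, "rejected") <- rejected
  d
}

#' @rdname read_dosage_table
#' @param dosage_table `data.frame` with columns `individual`, `marker`,
#'   `p11`, `p12`, `p22`.
#' @export
write_dosage_table <- function(dosage_table, path) {
  utils::write.table(
    dosage_table[, c("individual", "marker", "p11", "p12", "p22")],
    path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Extract analysis trios from a pedigree
#'
#' One trio per affected child whose father and mother are both present in
#' the family and of whom at least one is genotyped on the linkage
#' (microsatellite) markers. A family with several affected siblings
#' yields several trios sharing the same parents. Ineligible children are
#' skipped and counted in the report.
#'
#' @param ped Pedigree `data.frame` (see [read_pedfile()]).
#' @param ms_genotyped Logical vector along the rows of `ped`: is the
#'   individual genotyped on microsatellite markers?
#' @return `data.frame` with columns `family_id`, `child_id`, `father_id`,
#'   `mother_id`, `father_ms`, `mother_ms`; attribute `"report"` counts
#'   affected children skipped for missing parents or un-genotyped parents.
#' @export
extract_trios <- function(ped, ms_genotyped) {
  ms_genotyped <- rep_len(ms_genotyped, nrow(ped))
  key <- paste(ped$fid, ped$iid)
  ms <- stats::setNames(ms_genotyped, key)
  aff <- which(!is.na(ped$affection) & ped$affection == 2L)
  fkey <- paste(ped$fid, ped$father)[aff]
  mkey <- paste(ped$fid, ped$mother)[aff]
  has_parents <- ped$father[aff] != "0" & ped$mother[aff] != "0" &
    fkey %in% key & mkey %in% key
  parent_ms_f <- ifelse(has_parents, ms[fkey], FALSE)
  parent_ms_m <- ifelse(has_parents, ms[mkey], FALSE)
  eligible <- has_parents & (parent_ms_f | parent_ms_m)
  out <- data.frame(
    family_id = ped$fid[aff][eligible],
    child_id = ped$iid[aff][eligible],
    father_id = ped$father[aff][eligible],
    mother_id = ped$mother[aff][eligible],
    father_ms = as.logical(parent_ms_f[eligible]),
    mother_ms = as.logical(parent_ms_m[eligible]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "report") <- data.frame(
    n_affected = length(aff),
    n_trios = nrow(out),
    skipped_missing_parents = sum(!has_parents),
    skipped_no_ms_parent = sum(has_parents & !eligible),
    stringsAsFactors = FALSE)
  out
}

#' Serialize a simulated trio set to a pedigree
#'
#' Lays out each simulated trio as a three-member family (father `1`,
#' mother `2`, affected child `3`) with the microsatellite genotyped in
#' everybody and the SNP genotyped only in the child, matching the layout
#' a pedigree inference program would consume.
#'
#' @param trios Output of [simulate_trio_set()].
#' @return A pedigree `data.frame` with markers `snp` and `ms` (attribute
#'   `"markers"`), writable with [write_pedfile()].
#' @export
sim_trios_to_pedigree <- function(trios) {
  n <- nrow(trios)
  fid <- rep(trios$trio_id, each = 3)
  iid <- rep(c("1", "2", "3"), n)
  ped <- data.frame(
    fid = fid, iid = iid,
    father = rep(c("0", "0", "1"), n),
    mother = rep(c("0", "0", "2"), n),
    sex = rep(c(1L, 2L, 0L), n),
    affection = rep(c(0L, 0L, 2L), n),
    snp = as.vector(rbind(NA_character_, NA_character_, trios$child_snp)),
    ms = as.vector(rbind(paste0(trios$father_ms1, "/", trios$father_ms2),
                         paste0(trios$mother_ms1, "/", trios$mother_ms2),
                         paste0(trios$child_ms1, "/", trios$child_ms2))),
    stringsAsFactors = FALSE
  )
  attr(ped, "markers") <- c("snp", "ms")
  ped
}

#' Write per-marker association results as TSV
#'
#' Columns: `marker`, `chr`, `gm`, `pm`, `cc_chi2`, `cc_p`, `dtdt_chi2`,
#' `dtdt_p`, `mh_chi2`, `mh_p`, `direction`, `n_informative`. Missing
#' columns are filled with `NA` so partial pipelines still serialize.
#'
#' @param results `data.frame` of per-marker results.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  cols <- c("marker", "chr", "gm", "pm", "cc_chi2", "cc_p", "dtdt_chi2",
            "dtdt_p", "mh_chi2", "mh_p", "direction", "n_informative")
  for (cl in setdiff(cols, names(results))) results[[cl]] <- NA
  utils::write.table(results[, cols], path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}
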