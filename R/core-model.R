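#' SNP panel metadata
#'
#' Builds the per-SNP metadata table carried by a [genotype_matrix()]:
#' identifier, gene label, and major/minor alleles. The minor allele is
#' the allele counted by the 0/1/2 dosage coding.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param gene gene label per SNP.
#' @param allele_major,allele_minor single-character bases; must differ
#'   within each SNP.
#' @return A `data.frame` with one row per SNP.
#' @export
snp_info <- function(snp_id, gene, allele_major, allele_minor) {
  stopifnot(length(snp_id) > 0, !anyDuplicated(snp_id),
            all(nchar(snp_id) > 0))
  if (any(allele_major == allele_minor))
    stop("major and minor allele must differ for every SNP")
  data.frame(snp_id = as.character(snp_id), gene = as.character(gene),
             allele_major = as.character(allele_major),
             allele_minor = as.character(allele_minor),
             stringsAsFactors = FALSE)
}

#' Genotype matrix in minor-allele dosage coding
#'
#' Container for an individuals x SNPs matrix of minor-allele counts
#' (0, 1, 2), with `NA` as the missing-genotype sentinel (0 is a valid
#' dosage and is never used as a missing marker).
#'
#' @param dosage integer matrix, rows = individuals, columns = SNPs;
#'   entries in \{0, 1, 2, NA\}.
#' @param snps SNP metadata from [snp_info()]; row order must match the
#'   columns of `dosage`.
#' @param individuals character ids, one per row of `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps, individuals = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(individuals)) individuals <- as.character(seq_len(nrow(dosage)))
  stopifnot(ncol(dosage) == nrow(snps), length(individuals) == nrow(dosage))
  if (anyDuplicated(individuals)) stop("duplicate individual ids")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  rownames(dosage) <- as.character(individuals)
  colnames(dosage) <- snps$snp_id
  structure(dosage, snps = snps, class = c("genotype_matrix", "matrix"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%d missing calls)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
snps_of <- function(gm) attr(gm, "snps")

#' @export
`[.genotype_matrix` <- function(x, i, j, drop = FALSE) {
  m <- unclass(x)
  info <- snps_of(x)
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  sub <- m[i, j, drop = FALSE]
  jj <- match(colnames(sub), info$snp_id)
  genotype_matrix(sub, info[jj, , drop = FALSE], rownames(sub))
}

#' Read a genotype matrix
#'
#' Reads either a PLINK-style `.ped`/`.map` pair (whitespace-delimited,
#' two allele columns per SNP) or a delimited wide table with rows =
#' individuals and columns = SNP dosages in \{0, 1, 2, NA\}. For ped
#' input the minor allele of each SNP is determined from the control
#' subgroup when `status` is supplied (so odds ratios keep their
#' case-control orientation), otherwise from the full sample.
#'
#' @param path path to the `.ped` file or the delimited table.
#' @param format `"ped_map"` or `"delimited"`.
#' @param map_path path to the `.map` file (ped input only).
#' @param status optional named 0/1 vector (1 = case) used to pick the
#'   minor allele from controls.
#' @param gene optional gene labels per SNP (recycled).
#' @param sep field separator for delimited input.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("ped_map", "delimited"),
                           map_path = NULL, status = NULL, gene = "",
                           sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "delimited") {
    tab <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE)
    info <- snp_info(colnames(tab), gene = rep_len(gene, ncol(tab)),
                     allele_major = rep_len("A", ncol(tab)),
                     allele_minor = rep_len("B", ncol(tab)))
    return(genotype_matrix(as.matrix(tab), info, rownames(tab)))
  }
  if (is.null(map_path)) stop("ped_map format needs map_path")
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  snp_ids <- as.character(map[[2]])
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  ids <- ped[[2]]
  if (anyDuplicated(ids)) stop("duplicate individual ids in ped file")
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  if (ncol(al) != 2L * length(snp_ids))
    stop("ped/map mismatch: ", ncol(al), " allele columns for ",
         length(snp_ids), " SNPs")
  n <- nrow(al)
  dos <- matrix(NA_integer_, n, length(snp_ids))
  maj <- min_ <- character(length(snp_ids))
  is_control <- if (is.null(status)) rep(TRUE, n) else {
    st <- status[ids]
    if (anyNA(st)) stop("status vector does not cover all ped individuals")
    st == 0
  }
  for (j in seq_along(snp_ids)) {
    a1 <- al[, 2L * j - 1L]; a2 <- al[, 2L * j]
    miss <- a1 == "0" | a2 == "0"
    obs <- c(a1[!miss], a2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop("SNP ", snp_ids[j], " is not biallelic: ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0L) stop("SNP ", snp_ids[j], " has no calls")
    ctrl <- c(a1[!miss & is_control], a2[!miss & is_control])
    if (!length(ctrl)) ctrl <- obs
    cnt <- table(factor(ctrl, levels = alleles))
    # minor = least frequent in controls; deterministic tie-break by base
    mn <- alleles[which.min(cnt)]
    mj <- if (length(alleles) == 2L) setdiff(alleles, mn) else mn
    d <- (a1 == mn) + (a2 == mn)
    d[miss] <- NA_integer_
    dos[, j] <- as.integer(d)
    maj[j] <- mj; min_[j] <- mn
  }
  info <- snp_info(snp_ids, gene = rep_len(gene, length(snp_ids)),
                   allele_major = maj, allele_minor = min_)
  genotype_matrix(dos, info, ids)
}

#' Write a genotype matrix as a delimited wide table
#'
#' Inverse of `read_genotypes(format = "delimited")`: integer dosages
#' round-trip exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_genotypes <- function(gm, path, sep = ",") {
  tab <- data.frame(id = rownames(gm), unclass(gm)[, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/exposure table
#'
#' Expects a delimited file with header
#' `id,status,sex,age,smoking,alcohol`: `status` 1 = case, `sex` coded
#' `"M"`/`"F"` (or 1/0), `smoking` ever/never as 1/0, `alcohol`
#' regular/infrequent as 1/0 (may be missing).
#'
#' @param path file path.
#' @param sep field separator.
#' @return A `data.frame` (the cohort table).
#' @export
read_phenotypes <- function(path, sep = ",") {
  ct <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("id", "status", "sex", "age", "smoking", "alcohol")
  if (!all(need %in% names(ct)))
    stop("phenotype table must have columns: ", paste(need, collapse = ","))
  ct$id <- as.character(ct$id)
  if (is.numeric(ct$sex)) ct$sex <- ifelse(ct$sex == 1, "M", "F")
  ct$sex <- toupper(substr(ct$sex, 1, 1))
  validate_cohort(ct)
  ct
}

validate_cohort <- function(ct) {
  if (anyNA(ct$status) || anyNA(ct$sex)) stop("status and sex must be complete")
  if (!all(ct$status %in% 0:1)) stop("status must be 0/1")
  if (!all(ct$sex %in% c("M", "F"))) stop("sex must be M/F")
  if (any(ct$age <= 0, na.rm = TRUE)) stop("age must be positive")
  invisible(ct)
}

#' Write a result table as tab-separated text
#'
#' @param tab a data frame.
#' @param path output path.
#' @export
write_result_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict to complete cases shared by genotype and phenotype tables
#'
#' Keeps the individuals present in both tables that have a complete
#' genotype call at every SNP, matching the complete-call QC rule of a
#' fixed-panel candidate-gene study. Ids are joined by exact string
#' match.
#'
#' @param gm a [genotype_matrix()].
#' @param ct a cohort table (see [read_phenotypes()]).
#' @return A list with elements `gm`, `ct`, `n_removed`, and
#'   `removed_ids` (ids dropped for missing genotypes).
#' @export
filter_complete_cases <- function(gm, ct) {
  shared <- intersect(rownames(gm), ct$id)
  if (!length(shared)) stop("no shared individuals between tables")
  sub <- unclass(gm)[shared, , drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  removed <- shared[!complete]
  keep <- shared[complete]
  if (!length(keep)) stop("no individuals with complete genotypes")
  out_gm <- genotype_matrix(sub[keep, , drop = FALSE], snps_of(gm), keep)
  out_ct <- ct[match(keep, ct$id), , drop = FALSE]
  rownames(out_ct) <- NULL
  list(gm = out_gm, ct = out_ct, n_removed = length(removed),
       removed_ids = removed)
}

#' Select a sex stratum
#'
#' @param ct cohort table.
#' @param stratum `"entire"`, `"male"` or `"female"`.
#' @return Logical selector over the rows of `ct`.
#' @export
stratum_selector <- function(ct, stratum = c("entire", "male", "female")) {
  stratum <- match.arg(stratum)
  switch(stratum,
         entire = rep(TRUE, nrow(ct)),
         male = ct$sex == "M",
         female = ct$sex == "F")
}
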