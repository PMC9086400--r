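#' Read PLINK text PED/MAP genotypes
#'
#' Parses whitespace-delimited text PED (six leading columns, then two allele
#' columns per marker) and MAP (chrom, snp id, cM, bp) files into a
#' [geno_matrix()]. PED files carry no reference/alternate designation, so the
#' A allele of each SNP is the first non-missing allele encountered reading
#' samples in file order (stable across runs); `0` denotes a missing allele
#' and `0 0` a missing genotype. The PED family id column is used as the
#' population label.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [geno_matrix()]. Out-of-order map positions are sorted with a
#'   warning. A SNP with more than two distinct non-missing alleles is an
#'   error naming the SNP.
#' @export
read_ped_map <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = c("integer", "character",
                                              "numeric", "numeric"))
  names(map_raw) <- c("chrom", "snp_id", "cm", "pos_bp")
  n_snp <- nrow(map_raw)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * n_snp
  n_fields <- lengths(fields)
  if (any(n_fields != expected)) {
    bad <- which(n_fields != expected)[1]
    stop("PED row ", bad, " has ", n_fields[bad], " fields; expected ",
         expected, " for ", n_snp, " SNPs", call. = FALSE)
  }
  n_sample <- length(fields)
  meta <- t(vapply(fields, function(f) f[1:2], character(2)))
  allele_mat <- matrix(unlist(lapply(fields, function(f) f[-(1:6)])),
                       nrow = n_sample, byrow = TRUE)
  a1 <- allele_mat[, seq(1, 2 * n_snp, by = 2), drop = FALSE]
  a2 <- allele_mat[, seq(2, 2 * n_snp, by = 2), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    stop("half-missing genotype (one allele 0) at SNP ",
         map_raw$snp_id[which(half, arr.ind = TRUE)[1, 2]], call. = FALSE)
  }

  calls <- matrix(NA_integer_, n_sample, n_snp)
  allele_a <- character(n_snp)
  allele_b <- character(n_snp)
  for (j in seq_len(n_snp)) {
    obs <- c(rbind(a1[, j], a2[, j]))  # sample-major order
    seen <- unique(obs[!is.na(obs)])
    if (length(seen) > 2) {
      stop("SNP ", map_raw$snp_id[j], " has ", length(seen),
           " distinct alleles; biallelic data required", call. = FALSE)
    }
    aa <- if (length(seen) >= 1) seen[1] else NA_character_
    bb <- if (length(seen) == 2) seen[2] else NA_character_
    allele_a[j] <- ifelse(is.na(aa), "0", aa)
    allele_b[j] <- ifelse(is.na(bb), "0", bb)
    dose <- (a1[, j] == bb) + (a2[, j] == bb)
    dose[is.na(a1[, j])] <- NA_integer_
    if (is.na(bb)) dose <- ifelse(is.na(a1[, j]), NA_integer_, 0L)
    calls[, j] <- as.integer(dose)
  }

  samples <- tibble::tibble(sample_id = meta[, 2], population = meta[, 1])
  map <- tibble::tibble(snp_id = map_raw$snp_id, chrom = map_raw$chrom,
                        pos_bp = map_raw$pos_bp, cm = map_raw$cm,
                        allele_a = allele_a, allele_b = allele_b)
  geno_matrix(calls, samples, map)
}

#' Write PLINK text PED/MAP genotypes
#'
#' Inverse of [read_ped_map()]: genotype codes are expanded back to allele
#' pairs using the map's `allele_a`/`allele_b` columns (defaulting to "A"/"B"
#' symbols when absent), missing calls to `0 0`.
#'
#' @param gm A [geno_matrix()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  stopifnot(inherits(gm, "geno_matrix"))
  map <- gm$map
  aa <- if ("allele_a" %in% names(map)) map$allele_a else rep("A", nrow(map))
  bb <- if ("allele_b" %in% names(map)) map$allele_b else rep("B", nrow(map))
  bb[is.na(bb) | bb == "0"] <- aa[is.na(bb) | bb == "0"]  # monomorphic
  cm <- if ("cm" %in% names(map)) map$cm else 0
  utils::write.table(
    data.frame(map$chrom, map$snp_id, cm, map$pos_bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  n_snp <- nrow(map)
  lines <- vapply(seq_len(nrow(gm$samples)), function(i) {
    g <- gm$calls[i, ]
    x1 <- ifelse(is.na(g), "0", ifelse(g == 2, bb, aa))
    x2 <- ifelse(is.na(g), "0", ifelse(g >= 1, bb, aa))
    paste(c(gm$samples$population[i], gm$samples$sample_id[i],
            "0", "0", "0", "-9", rbind(x1, x2)), collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read genotypes from a VCF file
#'
#' Imports the GT field of a diploid VCF into a [geno_matrix()] with
#' `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA`. Multiallelic
#' records are skipped with a message giving their count. REF maps to the A
#' allele and ALT to the B allele.
#'
#' @param vcf_path Path to a VCF (v4.x) file.
#' @param population Population label applied to all samples (VCFs carry
#'   none); default "pop1".
#' @return A [geno_matrix()].
#' @export
read_vcf_genotypes <- function(vcf_path, population = "pop1") {
  stopifnot(file.exists(vcf_path))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (!"GT" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID &&
      !grepl("GT", vcf@gt[1, "FORMAT"])) {
    stop("VCF has no GT field", call. = FALSE)
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt == "0/0"] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt == "1/1"] <- 2L
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  map <- tibble::tibble(snp_id = ids,
                        chrom = as.integer(fix$CHROM),
                        pos_bp = as.numeric(fix$POS),
                        allele_a = fix$REF, allele_b = fix$ALT)
  samples <- tibble::tibble(sample_id = colnames(gt), population = population)
  geno_matrix(t(code), samples, map)
}
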