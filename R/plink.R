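#' Write a genotype panel as PLINK bed/bim/fam files
#'
#' Writes the binary SNP-major PLINK 1 format: `.bed` starts with the magic
#' bytes `0x6c 0x1b 0x01`, then one block of `ceiling(n/4)` bytes per SNP with
#' four 2-bit genotype codes per byte (low bits first). Allele counts count
#' the A1 allele (written as "A" in the `.bim`): count 2 is coded `00`, 1 is
#' `10`, 0 is `11`. The population label is stored in the family-ID column of
#' the `.fam`. The pedigree, if given, is written as a tab-separated table
#' `<prefix>.ped.tsv` with columns id, sire, dam, population (unknown parents
#' as `0`).
#'
#' @param panel a `genotype_panel`.
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` are created.
#' @param pedigree optional pedigree data frame (id, sire, dam, population,
#'   generation).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix, pedigree = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes
  n <- nrow(g)

  # .bed: 2-bit codes packed 4 per byte, LSB-first, SNP-major
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L) # allele count -> PLINK code
  n_bytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * n_bytes - n
  for (s in seq_len(ncol(g))) {
    codes <- c(code[as.character(g[, s])], rep(0L, pad))
    m <- matrix(codes, nrow = 4L)
    bytes <- m[1, ] + 4L * m[2, ] + 16L * m[3, ] + 64L * m[4, ]
    writeBin(as.raw(bytes), con)
  }

  bim <- data.frame(chrom = panel$snp_map$chromosome,
                    snp_id = panel$snp_map$snp_id,
                    genetic_position = panel$snp_map$genetic_position,
                    position = panel$snp_map$position,
                    A1 = "A", A2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = panel$population, iid = panel$individual_ids,
                    father = 0L, mother = 0L, sex = 0L, phenotype = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(pedigree)) {
    ped <- data.frame(id = pedigree$id,
                      sire = ifelse(is.na(pedigree$sire), "0", pedigree$sire),
                      dam = ifelse(is.na(pedigree$dam), "0", pedigree$dam),
                      population = pedigree$population)
    utils::write.table(ped, paste0(prefix, ".ped.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
  }
  invisible(prefix)
}

#' Read PLINK bed/bim/fam files into a genotype panel
#'
#' Inverse of [write_plink()]: `read_plink(write_plink(panel, p))` reproduces
#' the allele-count matrix, individual ids, SNP map and population labels
#' exactly. Malformed magic bytes or a truncated `.bed` payload raise a format
#' error naming the byte offset.
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` triplet.
#' @return list with `panel` (a `genotype_panel`) and `pedigree` (data frame
#'   or `NULL` when no `<prefix>.ped.tsv` is present).
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chromosome", "snp_id", "genetic_position", "position",
                  "A1", "A2")
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           colClasses = c("character", "character", "character",
                                          "character", "character", "character"))
  n <- nrow(fam)
  S <- nrow(bim)
  n_bytes <- ceiling(n / 4)

  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = file.size(paste0(prefix, ".bed")) + 1L)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file: bad magic bytes at offset 0", call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("unsupported bed mode byte at offset 2 (need SNP-major 0x01)",
         call. = FALSE)
  }
  expected <- 3L + n_bytes * S
  if (length(raw) < expected) {
    stop(sprintf("truncated bed payload: expected %d bytes, file ends at offset %d",
                 expected, length(raw)), call. = FALSE)
  }
  payload <- as.integer(raw[4:expected])
  # unpack 2-bit codes, LSB first
  q <- matrix(0L, nrow = 4L * n_bytes, ncol = S)
  pay <- matrix(payload, nrow = n_bytes)
  q[seq(1, by = 4, length.out = n_bytes), ] <- pay %% 4L
  q[seq(2, by = 4, length.out = n_bytes), ] <- (pay %/% 4L) %% 4L
  q[seq(3, by = 4, length.out = n_bytes), ] <- (pay %/% 16L) %% 4L
  q[seq(4, by = 4, length.out = n_bytes), ] <- (pay %/% 64L) %% 4L
  q <- q[seq_len(n), , drop = FALSE]
  decode <- c(2L, NA_integer_, 1L, 0L) # code 0,1,2,3 -> A1 count
  geno <- matrix(decode[q + 1L], nrow = n)
  if (anyNA(geno)) stop("missing genotype codes (01) are not supported",
                        call. = FALSE)

  snp_map <- bim[, c("snp_id", "chromosome", "position", "genetic_position")]
  panel <- genotype_panel(geno, fam[[2]], fam[[1]], snp_map)
  ped_path <- paste0(prefix, ".ped.tsv")
  pedigree <- NULL
  if (file.exists(ped_path)) {
    pedigree <- utils::read.table(ped_path, sep = "\t", header = TRUE,
                                  colClasses = "character")
    pedigree$sire[pedigree$sire == "0"] <- NA_character_
    pedigree$dam[pedigree$dam == "0"] <- NA_character_
  }
  list(panel = panel, pedigree = pedigree)
}
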