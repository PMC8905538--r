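#' Read a genotype matrix from VCF, PLINK binary or TSV dosage
#'
#' Codes count copies of the alternate allele (VCF ALT / PLINK .bim A1), so
#' MAF and GRM construction are orientation-consistent; the orientation is
#' recorded on the returned object. Positions are 1-based as in VCF. Only
#' diploid biallelic records are accepted.
#'
#' @param path file path (for `plink-bed`, the `.bed` path; the `.bim` and
#'   `.fam` siblings must sit alongside).
#' @param format one of "vcf", "plink-bed", "tsv-dosage".
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "plink-bed", "tsv-dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         "vcf" = read_genotypes_vcf(path),
         "plink-bed" = read_genotypes_bed(path),
         "tsv-dosage" = read_genotypes_dosage(path))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)      # single-record VCFs drop to a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) at ",
         paste(fix$CHROM[multi], fix$POS[multi], sep = ":", collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  code_one <- function(g) {
    a <- strsplit(g, "[/|]")[[1]]
    if (length(a) != 2) stop("non-diploid genotype '", g, "'")
    if (any(a == ".")) return(NA_integer_)
    sum(as.integer(a))
  }
  codes <- t(apply(gt, c(1, 2), function(g)
    if (is.na(g)) NA_integer_ else code_one(g)))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  colnames(codes) <- ids
  genotype_matrix(codes,
                  snp_info = data.frame(id = ids, chr = fix$CHROM,
                                        pos = as.integer(fix$POS),
                                        ref = fix$REF, alt = fix$ALT),
                  counted_allele = "alt")
}

#' Write a genotype matrix to a minimal VCF 4.2 file
#' @param genotypes a `genotype_matrix`.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  G <- genotypes$geno; info <- genotypes$snp_info
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    gs <- ifelse(is.na(g), "./.", gt_str[g + 1])
    lines <- c(lines, paste(c(info$chr[j], info$pos[j], info$id[j],
                              info$ref[j], info$alt[j], ".", "PASS", ".",
                              "GT", gs), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

read_genotypes_bed <- function(path) {
  stem <- sub("\\.bed$", "", path)
  bim <- utils::read.table(paste0(stem, ".bim"), stringsAsFactors = FALSE,
                           col.names = c("chr", "id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paste0(stem, ".fam"), stringsAsFactors = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", path)
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  n <- nrow(fam); m <- nrow(bim)
  bps <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bps * m) stop("truncated .bed: ", path)
  # 2-bit codes per animal, LSB first: 00=hom a1, 01=missing, 10=het, 11=hom a2
  lut <- c(2L, NA_integer_, 1L, 0L)                  # a1 dosage by code + 1
  codes <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    bytes <- as.integer(body[((j - 1) * bps + 1):(j * bps)])
    tb <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L, (bytes %/% 16L) %% 4L,
                bytes %/% 64L)
    codes[, j] <- lut[as.vector(tb)[seq_len(n)] + 1L]
  }
  rownames(codes) <- as.character(fam[[2]])
  colnames(codes) <- bim$id
  genotype_matrix(codes,
                  snp_info = data.frame(id = bim$id, chr = as.character(bim$chr),
                                        pos = bim$pos, ref = bim$a2,
                                        alt = bim$a1),
                  counted_allele = "alt")
}

#' Write a genotype matrix as a PLINK binary triplet (SNP-major)
#' @param genotypes a `genotype_matrix` (codes count the A1 allele).
#' @param stem path stem; writes stem.bed/.bim/.fam.
#' @export
write_genotypes_bed <- function(genotypes, stem) {
  G <- genotypes$geno; info <- genotypes$snp_info
  n <- nrow(G)
  utils::write.table(data.frame(info$chr, info$id, 0, info$pos, info$alt,
                                info$ref),
                     paste0(stem, ".bim"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE, sep = "\t")
  utils::write.table(data.frame(rownames(G), rownames(G), 0, 0, 0, -9),
                     paste0(stem, ".fam"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE, sep = "\t")
  enc <- c(`2` = 0L, `1` = 2L, `0` = 3L)             # inverse of the read LUT
  con <- file(paste0(stem, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bps <- ceiling(n / 4)
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    tb <- ifelse(is.na(g), 1L, enc[as.character(g)])
    tb <- c(tb, rep(0L, bps * 4 - n))
    bytes <- tb[seq(1, length(tb), 4)] + 4L * tb[seq(2, length(tb), 4)] +
      16L * tb[seq(3, length(tb), 4)] + 64L * tb[seq(4, length(tb), 4)]
    writeBin(as.raw(bytes), con)
  }
  invisible(paste0(stem, ".bed"))
}

read_genotypes_dosage <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  codes <- as.matrix(d)
  storage.mode(codes) <- "integer"
  genotype_matrix(codes, counted_allele = "alt")
}

#' Read a taxon abundance table from TSV
#'
#' Rows are samples (first column = sample ID), columns taxa. Integer tables
#' are taken as counts and closed to relative abundances; tables already in
#' \[0,1\] are returned unchanged.
#'
#' @param path TSV path.
#' @param level taxonomy level tag.
#' @return an `abundance_table`.
#' @export
read_abundance <- function(path, level = "order") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- ids
  if (any(m < 0)) stop("negative abundance cells")
  if (all(m == floor(m)) && any(m > 1)) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    m <- m / rs
  }
  abundance_table(m, level = level)
}

#' Write an abundance table to TSV
#' @param table an `abundance_table`.
#' @param path output path.
#' @export
write_abundance <- function(table, path) {
  d <- data.frame(sample_id = rownames(table$ab), table$ab,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a co-occurrence graph to GraphML
#'
#' Nodes carry `abundance_class` in \{high, low, other\}; edges carry integer
#' co-occurrence `weight`. An empty graph yields valid GraphML with zero
#' nodes; isolated nodes are emitted.
#'
#' @param graph an igraph graph from [build_graph()].
#' @param path output path.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML co-occurrence graph
#' @param path GraphML path.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write a mined network set to TSV (one row per record)
#' @param networks a `mined_networks` object.
#' @param path output path.
#' @export
write_networks_tsv <- function(networks, path) {
  df <- as.data.frame(networks)
  df <- df[, c("layer", "pairs", "a", "b", "c", "d", "fisher_p", "z",
               "adjusted_p", "direction")]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a case/control assignment to TSV
#' @param assignment a `case_control` data.frame.
#' @param path output path.
#' @export
write_assignment_tsv <- function(assignment, path) {
  utils::write.table(assignment, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
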