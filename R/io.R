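# Standard-format I/O, SNP QC, SNP-to-gene mapping and relatedness pruning.
#
# The PLINK-1 bed codec is written out by hand (2 bits per genotype,
# SNP-major): 00 = two copies of allele1, 10 = het, 11 = zero copies,
# 01 = missing.  Coordinates are 1-based inclusive internally.

# 256 x 4 lookup: byte value -> allele1 dosage of the 4 packed genotypes.
.plink_decode_table <- local({
  tab <- matrix(NA_real_, 256, 4)
  map <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)   # 2-bit code -> dosage
  for (b in 0:255) {
    for (g in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * g), 3L)
      tab[b + 1L, g + 1L] <- map[[as.character(code)]]
    }
  }
  tab
})

#' Write genotypes as a PLINK-1 bed/bim/fam triplet
#'
#' Hard-call export: dosages are rounded to 0/1/2; NA becomes the PLINK
#' missing code.  bim columns: chr, snp_id, cM (0), pos, allele1 (effect,
#' counted by the dosage), allele2.
#'
#' @param genotypes a `genotypes` object (`dosage`, `snps`, `ids`).
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return prefix, invisibly.
#' @export
write_plink <- function(genotypes, prefix) {
  X <- round(genotypes$dosage)
  n <- nrow(X); m <- ncol(X)
  snps <- genotypes$snps
  # fam: FID IID father mother sex pheno
  fam <- data.frame(genotypes$ids, genotypes$ids, 0L, 0L, 0L, -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  bim <- data.frame(snps$chr, snps$snp_id, 0L, snps$pos, snps$a1, snps$a2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  # encode dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, n, m)
  code[!is.na(X) & X == 2] <- 0L
  code[!is.na(X) & X == 1] <- 2L
  code[is.na(X)] <- 1L
  nb <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * nb - n
  for (j in seq_len(m)) {
    cj <- c(code[, j], integer(pad))
    idx <- matrix(cj, nrow = 4L)
    bytes <- idx[1, ] + idx[2, ] * 4L + idx[3, ] * 16L + idx[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read genotypes from a PLINK-1 triplet or a dosage TSV
#'
#' For a PLINK prefix, decodes the SNP-major 2-bit encoding bit-exactly;
#' missing genotypes come back as NA (use [impute_mean()] before matrix
#' algebra).  A path ending in `.tsv` is read as a dosage table
#' (first column individual id, remaining columns one SNP each).
#'
#' @param path PLINK prefix (no extension) or a `.tsv` dosage file.
#' @return a `genotypes` object.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.tsv$", path)) return(read_dosage_tsv(path))
  read_plink(path)
}

#' @rdname read_genotypes
#' @param prefix PLINK path prefix.
#' @export
read_plink <- function(prefix) {
  bedf <- paste0(prefix, ".bed")
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE)
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bedf, "raw", n = file.size(bedf))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop_param("%s: PLINK bed magic bytes absent", bedf)
  if (raw[3] != as.raw(0x01))
    stop_param("%s: only SNP-major bed files are supported", bedf)
  nb <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != nb * m)
    stop_param("bed size (%d bytes) does not match bim/fam (%d SNPs x %d ids)",
               length(body), m, n)
  vals <- .plink_decode_table[as.integer(body) + 1L, , drop = FALSE]
  # vals is (nb*m) x 4; per SNP the nb rows unpack to 4*nb genotypes
  X <- matrix(t(vals), nrow = 4L * nb)[seq_len(n), , drop = FALSE]
  dim(X) <- c(n, m)
  ids <- as.character(fam[[2]])
  if (anyDuplicated(ids)) stop_param("duplicated individual IDs in fam")
  if (anyDuplicated(bim[[2]])) stop_param("duplicated SNP IDs in bim")
  rownames(X) <- ids
  colnames(X) <- as.character(bim[[2]])
  snps <- data.frame(snp_id = as.character(bim[[2]]), chr = bim[[1]],
                     pos = bim[[4]], a1 = as.character(bim[[5]]),
                     a2 = as.character(bim[[6]]), stringsAsFactors = FALSE)
  p <- colMeans(X, na.rm = TRUE) / 2
  snps$maf <- pmin(p, 1 - p)
  snps$info <- 1
  structure(list(dosage = X, snps = snps, ids = ids), class = "genotypes")
}

#' @rdname read_genotypes
#' @export
read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path)
  ids <- as.character(dt[[1]])
  X <- as.matrix(dt[, -1, drop = FALSE])
  rownames(X) <- ids
  p <- colMeans(X, na.rm = TRUE) / 2
  snps <- data.frame(snp_id = colnames(X), chr = 1L, pos = seq_len(ncol(X)),
                     a1 = "A", a2 = "G", maf = pmin(p, 1 - p), info = 1,
                     stringsAsFactors = FALSE)
  structure(list(dosage = X, snps = snps, ids = ids), class = "genotypes")
}

#' @rdname read_genotypes
#' @param genotypes a `genotypes` object.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  dt <- data.table::data.table(id = genotypes$ids)
  dt <- cbind(dt, data.table::as.data.table(genotypes$dosage))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @param source description field (2nd GMT column), recycled.
#' @export
write_gmt <- function(sets, path, source = "pathrha") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, source, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene coordinate table
#'
#' TSV with columns gene_id, chr, start, end (1-based inclusive).
#' @param path file path.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  g <- as.data.frame(data.table::fread(path))
  names(g)[1:4] <- c("gene_id", "chr", "start", "end")
  if (any(g$start > g$end)) stop_param("gene table has start > end rows")
  g
}

#' SNP quality-control filter
#'
#' Keeps SNPs with `maf >= maf_min` and `info >= info_min`, both bounds
#' inclusive.
#'
#' @param snps data.frame with `maf` and `info` columns.
#' @param maf_min,info_min inclusive thresholds in `[0, 1]`.
#' @return integer vector of kept row indices.
#' @export
qc_filter <- function(snps, maf_min = 0.01, info_min = 0.8) {
  if (maf_min < 0 || maf_min > 1 || info_min < 0 || info_min > 1)
    stop_param("thresholds must be in [0, 1]")
  kept <- which(snps$maf >= maf_min & snps$info >= info_min)
  if (!length(kept)) warning("qc_filter removed every SNP")
  kept
}

#' Map SNPs to genes by position
#'
#' SNP s maps to gene g iff chromosomes match and
#' `start - window <= pos(s) <= end + window` (1-based inclusive); a SNP
#' may map to several genes.  Default window 0 kb = strict genic region.
#'
#' @param snps data.frame with `chr`, `pos`.
#' @param genes data.frame with `gene_id`, `chr`, `start`, `end`.
#' @param window_kb flanking window in kilobases (>= 0).
#' @return named list: gene_id -> integer vector of SNP row indices.
#' @export
map_snps_to_genes <- function(snps, genes, window_kb = 0) {
  if (window_kb < 0) stop_param("window_kb must be >= 0")
  w <- window_kb * 1000
  out <- lapply(seq_len(nrow(genes)), function(i) {
    which(snps$chr == genes$chr[i] &
          snps$pos >= genes$start[i] - w &
          snps$pos <= genes$end[i] + w)
  })
  names(out) <- genes$gene_id
  out
}

#' SNP index set of a pathway
#'
#' Union of the SNP sets of the pathway's genes under a gene map.
#' @param pathway_genes character vector of gene ids.
#' @param gene_map output of [map_snps_to_genes()].
#' @return sorted integer vector of SNP indices.
#' @export
pathway_snps <- function(pathway_genes, gene_map) {
  sort(unique(unlist(gene_map[intersect(pathway_genes, names(gene_map))])))
}

#' Prune related individuals from a GRM
#'
#' Greedy analogue of GCTA's `--grm-cutoff`: while any off-diagonal
#' relatedness exceeds `cutoff`, drop the individual involved in the most
#' offending pairs (ties: higher mean relatedness among offenders, then
#' later ID order).  Guarantees no remaining pair exceeds the cutoff and
#' approximately maximizes the retained sample.
#'
#' @param grm a `grm` object or a plain symmetric matrix.
#' @param cutoff positive relatedness threshold (GCTA default-style 0.025).
#' @return integer vector of kept individual indices (sorted).
#' @export
prune_related <- function(grm, cutoff = 0.025) {
  if (cutoff <= 0) stop_param("cutoff must be > 0")
  A <- if (inherits(grm, "grm")) grm$A else grm
  n <- nrow(A)
  off <- A; diag(off) <- -Inf
  alive <- rep(TRUE, n)
  repeat {
    bad <- which(alive)[rowSums(off[alive, alive, drop = FALSE] > cutoff) > 0]
    if (!length(bad)) break
    counts <- vapply(bad, function(i)
      sum(off[i, alive] > cutoff), 0)
    meanrel <- vapply(bad, function(i) {
      v <- off[i, alive]; mean(v[v > cutoff])
    }, 0)
    ord <- order(-counts, -meanrel, -bad)   # most pairs, then most related, then later ID
    alive[bad[ord[1]]] <- FALSE
  }
  which(alive)
}

#' Read / write a GRM in GCTA text format
#'
#' `<prefix>.grm.gz`: gzipped lower-triangle text, columns i, j, n_snps,
#' value; `<prefix>.grm.id`: FID/IID table.
#'
#' @param grm a `grm` object (see [compute_grm()]).
#' @param prefix path prefix.
#' @return prefix (write) / `grm` object (read).
#' @export
write_grm_gcta <- function(grm, prefix) {
  n <- nrow(grm$A)
  i <- rep(seq_len(n), seq_len(n))
  j <- sequence(seq_len(n))
  dt <- data.table::data.table(i = i, j = j, n_snps = grm$n_snps,
                               value = grm$A[cbind(i, j)])
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  utils::write.table(format(dt, scientific = FALSE, trim = TRUE), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  close(con)
  data.table::fwrite(data.frame(grm$ids, grm$ids), paste0(prefix, ".grm.id"),
                     sep = "\t", col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_gcta
#' @export
read_grm_gcta <- function(prefix) {
  ids <- data.table::fread(paste0(prefix, ".grm.id"), header = FALSE)[[2]]
  n <- length(ids)
  tri <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")))
  A <- matrix(0, n, n)
  A[cbind(tri[[1]], tri[[2]])] <- tri[[4]]
  A[cbind(tri[[2]], tri[[1]])] <- tri[[4]]
  structure(list(A = A, ids = as.character(ids),
                 n_snps = tri[[3]][1]), class = "grm")
}
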