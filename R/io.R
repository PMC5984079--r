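#' @importFrom VariantAnnotation readVcf geno
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom GenomicRanges seqnames start
#' @importFrom utils write.table read.delim
NULL

tsvWrite <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Write a cohort as a plain-text fixture
#'
#' Emits the four pipeline inputs: a VCF v4.2 with GT-only genotypes (the
#' ALT allele carries the stored dosage; no date header line, so repeated
#' writes of the same cohort are byte-identical), a tab-separated variant
#' annotation table, a tab-separated phenotype table, and one gene-set file
#' per set (first line the set name, then one gene symbol per line).
#'
#' @param cohort a [BurdenCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
writeFixture <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create directory '%s'", dir))
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             annotations = file.path(dir, "annotations.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  writeGenotypesVcf(cohort, paths[["vcf"]])
  rd <- rowData(cohort)
  ann <- data.frame(chrom = rd$chrom, pos = rd$pos, ref = rd$ref,
                    alt = rd$alt, gene = rd$gene,
                    consequence = rd$consequence, sift = rd$sift,
                    pph2_div = rd$pph2_div, pph2_var = rd$pph2_var,
                    lrt = rd$lrt, mutation_taster = rd$mutation_taster,
                    stringsAsFactors = FALSE)
  tsvWrite(ann, paths[["annotations"]])
  ph <- as.data.frame(colData(cohort))
  ph <- cbind(sample_id = rownames(ph), ph)
  rownames(ph) <- NULL
  tsvWrite(ph, paths[["phenotypes"]])
  for (nm in names(geneSets(cohort))) {
    p <- file.path(dir, sprintf("geneset_%s.txt", nm))
    writeLines(c(nm, geneSets(cohort)[[nm]]), p)
    paths[[paste0("geneset_", nm)]] <- p
  }
  invisible(paths)
}

# GT-only VCF v4.2 emitter. Parsing is delegated to VariantAnnotation; this
# writer only formats the matrix the simulator produced.
writeGenotypesVcf <- function(cohort, path) {
  d <- dosage(cohort)
  rd <- rowData(cohort)
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  contigs <- unique(as.character(rd$chrom))
  header <- c("##fileformat=VCFv4.2",
              "##source=rvburden",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              sprintf("##contig=<ID=%s>", contigs),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- paste(rd$chrom, rd$pos, rownames(d), rd$ref, rd$alt, ".", "PASS",
                ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
}

#' Read a cohort from fixture files
#'
#' Parses the VCF through `VariantAnnotation::readVcf`, joins the
#' annotation table by chrom/pos/ref/alt key, attaches phenotypes and gene
#' sets, classifies variants and computes allele frequencies.
#'
#' @param vcf path to a VCF with GT genotypes (biallelic SNVs, diploid).
#' @param annotations path to the tab-separated annotation table (columns
#'   chrom, pos, ref, alt, gene, consequence and the five predictor
#'   verdict columns).
#' @param phenotypes path to the tab-separated phenotype table
#'   (`sample_id` plus one column per trait).
#' @param geneSetFiles character vector of gene-set file paths (first line
#'   the set name, then one gene symbol per line).
#' @param traitTypes optional named vector of trait types; inferred when
#'   `NULL`.
#' @return a [BurdenCohort-class].
#' @export
readCohort <- function(vcf, annotations, phenotypes,
                       geneSetFiles = character(), traitTypes = NULL) {
  for (p in c(vcf, annotations, phenotypes, geneSetFiles))
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  v <- VariantAnnotation::readVcf(vcf, genome = "synthetic")
  gt <- VariantAnnotation::geno(v)$GT
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  d[gt %in% c("0/0", "0|0")] <- 0
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  d[gt %in% c("1/1", "1|1")] <- 2
  rr <- SummarizedExperiment::rowRanges(v)
  key <- sprintf("%s:%d_%s/%s", as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr),
                 as.character(rr$REF),
                 vapply(rr$ALT, function(a) as.character(a)[1], ""))
  ann <- utils::read.delim(annotations, stringsAsFactors = FALSE,
                           colClasses = c(
                             chrom = "character", ref = "character",
                             alt = "character", gene = "character"))
  annKey <- sprintf("%s:%d_%s/%s", ann$chrom, ann$pos, ann$ref, ann$alt)
  idx <- match(key, annKey)
  if (anyNA(idx))
    stop(sprintf("%d VCF record(s) missing from the annotation table",
                 sum(is.na(idx))))
  ann <- ann[idx, , drop = FALSE]
  rownames(d) <- key
  vi <- DataFrame(variant_id = key, ann, row.names = key)
  ph <- utils::read.delim(phenotypes, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(ph))
    stop("phenotype table needs a sample_id column")
  pidx <- match(colnames(d), ph$sample_id)
  if (anyNA(pidx)) stop("phenotype table is missing samples from the VCF")
  ph <- ph[pidx, setdiff(colnames(ph), "sample_id"), drop = FALSE]
  rownames(ph) <- colnames(d)
  gs <- list()
  for (p in geneSetFiles) {
    ln <- readLines(p)
    ln <- ln[nzchar(trimws(ln))]
    gs <- c(gs, geneSetDefinition(trimws(ln[1]), trimws(ln[-1])))
  }
  BurdenCohort(d, vi, ph, geneSets = gs, traitTypes = traitTypes)
}
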