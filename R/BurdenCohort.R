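#' Construct a BurdenCohort
#'
#' @param dosage integer/numeric matrix of minor-allele dosages, variants in
#'   rows and samples in columns; values in \{0, 1, 2\} or `NA`.
#' @param variantInfo `DataFrame`/`data.frame` of per-variant annotation,
#'   one row per variant. Expected columns include `gene`, `consequence` and
#'   the five predictor verdict columns
#'   (`sift`, `pph2_div`, `pph2_var`, `lrt`, `mutation_taster`).
#' @param phenotypes `DataFrame`/`data.frame` of per-sample traits, one row
#'   per sample, `NA` allowed.
#' @param geneSets named list of character vectors of gene symbols.
#' @param traitTypes named character vector mapping trait names to
#'   `"binary"` or `"quantitative"`; inferred from the columns when `NULL`
#'   (columns whose non-missing values are all 0/1 are binary).
#'
#' @return A [BurdenCohort-class] object. Functional classes and
#'   allele-frequency summaries (`maf`, `mac`, `is_singleton`, `is_rare`)
#'   are derived and stored in `rowData` when the inputs allow it.
#' @export
BurdenCohort <- function(dosage, variantInfo = NULL, phenotypes = NULL,
                         geneSets = list(), traitTypes = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("var%06d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("S%05d", seq_len(ncol(dosage)))
  rd <- if (is.null(variantInfo)) DataFrame(row.names = rownames(dosage))
        else DataFrame(variantInfo, row.names = rownames(dosage))
  cd <- if (is.null(phenotypes)) DataFrame(row.names = colnames(dosage))
        else DataFrame(phenotypes, row.names = colnames(dosage))
  if (is.null(traitTypes)) traitTypes <- inferTraitTypes(cd)
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowData = rd, colData = cd)
  obj <- new("BurdenCohort", se)
  metadata(obj)$geneSets <- lapply(geneSets, as.character)
  metadata(obj)$traitTypes <- traitTypes
  if (all(c("consequence") %in% colnames(rd)) &&
      !"functional_class" %in% colnames(rd)) {
    verd <- as.matrix(as.data.frame(rd[, intersect(PREDICTORS, colnames(rd))]))
    rowData(obj)$functional_class <-
      classifyVariants(rd$consequence, verd)
  }
  # updateFrequencies ends in a rowData<- replacement, which runs the
  # class validity method; no second explicit validation needed
  updateFrequencies(obj)
}

inferTraitTypes <- function(cd) {
  tt <- vapply(colnames(cd), function(nm) {
    v <- cd[[nm]]
    v <- v[!is.na(v)]
    if (is.numeric(v) && length(v) && all(v %in% c(0, 1))) "binary"
    else "quantitative"
  }, character(1))
  names(tt) <- colnames(cd)
  tt
}

#' Accessors for BurdenCohort
#'
#' `dosage()` returns the variants x samples minor-allele dosage matrix;
#' `variantInfo()` the per-variant annotation `DataFrame`; `phenotypes()`
#' the per-sample trait table; `geneSets()` the named list of gene sets;
#' `traitTypes()` the named trait-type vector.
#'
#' @param x a [BurdenCohort-class].
#' @return See individual descriptions.
#' @name cohort-accessors
#' @aliases dosage variantInfo phenotypes geneSets traitTypes
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname cohort-accessors
#' @export
setMethod("dosage", "BurdenCohort", function(x) assay(x, "dosage"))

#' @rdname cohort-accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname cohort-accessors
#' @export
setMethod("variantInfo", "BurdenCohort", function(x) rowData(x))

#' @rdname cohort-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname cohort-accessors
#' @export
setMethod("phenotypes", "BurdenCohort", function(x) colData(x))

#' @rdname cohort-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname cohort-accessors
#' @export
setMethod("geneSets", "BurdenCohort", function(x) metadata(x)$geneSets)

#' @rdname cohort-accessors
#' @export
setGeneric("traitTypes", function(x) standardGeneric("traitTypes"))
#' @rdname cohort-accessors
#' @export
setMethod("traitTypes", "BurdenCohort", function(x) metadata(x)$traitTypes)

#' @describeIn BurdenCohort compact display of cohort dimensions, class
#'   counts and trait summary.
#' @param object a `BurdenCohort`.
#' @export
setMethod("show", "BurdenCohort", function(object) {
  cat(sprintf("BurdenCohort: %d variants x %d samples\n",
              nrow(object), ncol(object)))
  rd <- rowData(object)
  if ("functional_class" %in% colnames(rd)) {
    tab <- table(factor(rd$functional_class, levels = FUNCTIONAL_CLASSES))
    cat("  functional classes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  if ("is_rare" %in% colnames(rd))
    cat(sprintf("  rare (MAF<1%%): %d  singletons: %d\n",
                sum(rd$is_rare, na.rm = TRUE),
                sum(rd$is_singleton, na.rm = TRUE)))
  gs <- geneSets(object)
  if (length(gs))
    cat("  gene sets:",
        paste(sprintf("%s (%d genes)", names(gs), lengths(gs)),
              collapse = ", "), "\n")
  tt <- traitTypes(object)
  if (length(tt))
    cat("  traits:",
        paste(sprintf("%s[%s]", names(tt), substr(tt, 1, 1)),
              collapse = " "), "\n")
  invisible(NULL)
})

updateFrequencies <- function(cohort) {
  fr <- computeFrequencies(dosage(cohort))
  rd <- rowData(cohort)
  for (nm in colnames(fr)) rd[[nm]] <- fr[[nm]]
  rowData(cohort) <- rd            # single assignment: one validation pass
  cohort
}

#' Define a gene set
#'
#' Small validated constructor for gene-set definitions.
#'
#' @param name gene-set name.
#' @param genes character vector of gene symbols; must be non-empty with no
#'   duplicates.
#' @return named list of length one suitable for `geneSets`.
#' @export
geneSetDefinition <- function(name, genes) {
  genes <- as.character(genes)
  if (!nzchar(name)) stop("gene set name must be non-empty")
  if (!length(genes)) stop(sprintf("gene set '%s' is empty", name))
  if (anyDuplicated(genes))
    stop(sprintf("gene set '%s' has duplicate symbols", name))
  stats::setNames(list(genes), name)
}
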