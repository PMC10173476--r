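#' Feature-by-sample expression table with annotation
#'
#' The central data container of the package, loosely modelled on edgeR's
#' `DGEList`: a non-negative numeric matrix of expression values plus a
#' feature annotation and a sample sheet, and a unit tag (`"counts"`,
#' `"rpm"` or `"tpm"`). Raw count tables hold integers; tables that have
#' been through the subgenome-mismatch correction may hold fractional
#' values and carry `corrected = TRUE`.
#'
#' @param counts numeric matrix, features in rows, samples in columns.
#' @param features data.frame with columns `feature_id`, `feature_class`
#'   (`hc_gene`, `lc_gene` or `te_family`), `subgenome` (`A`, `B`, `D`,
#'   `un`), `chromosome`, `order_index` (non-negative position rank along
#'   the chromosome) and `length_bp` (positive, may be `NA` for TE
#'   families). Extra columns (e.g. `te_family`) are carried through.
#' @param samples data.frame with columns `sample_id`, `genotype_id`,
#'   `tissue` (`leaf`/`grain`), `generation`, `role` (`diploid_parent`,
#'   `tetraploid_parent`, `synthetic`, `natural_hexaploid` or
#'   `in_silico_parent`) and `replicate_of`. Optional columns
#'   `diploid_parent` / `tetraploid_parent` name the parental genotypes of
#'   synthetic samples; `lib_size` records the original library depth.
#' @param unit one of `"counts"`, `"rpm"`, `"tpm"`.
#' @param corrected logical; has the subgenome-mismatch correction been
#'   applied? Guards against double application.
#' @return an object of class `count_table`.
#' @seealso [load_dataset()], [normalize_expression()]
#' @export
count_table <- function(counts, features, samples, unit = "counts",
                        corrected = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  rownames(features) <- NULL
  rownames(samples) <- NULL
  if (is.null(rownames(counts))) rownames(counts) <- features$feature_id
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  x <- structure(
    list(counts = counts, features = features, samples = samples,
         unit = unit, corrected = isTRUE(corrected)),
    class = "count_table")
  validate_count_table(x)
  x
}

#' Validate a count_table against its invariants
#'
#' Checks matrix/annotation agreement, controlled vocabularies, uniqueness
#' of identifiers, non-negativity and per-chromosome ordering. Errors name
#' the offending row or sample.
#'
#' @param x a [count_table()].
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_count_table <- function(x) {
  stopifnot(inherits(x, "count_table"))
  counts <- x$counts
  fe <- x$features
  sa <- x$samples
  if (!x$unit %in% .UNITS)
    stop("unknown unit '", x$unit, "'")
  if (!is.numeric(counts))
    stop("count matrix must be numeric")
  if (anyNA(counts))
    stop("count matrix contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at feature '", rownames(counts)[bad[1]],
         "', sample '", colnames(counts)[bad[2]], "'")
  }
  req_fe <- c("feature_id", "feature_class", "subgenome", "chromosome",
              "order_index", "length_bp")
  miss <- setdiff(req_fe, names(fe))
  if (length(miss))
    stop("feature annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(fe) != nrow(counts))
    stop("feature annotation has ", nrow(fe), " rows but matrix has ",
         nrow(counts))
  if (anyDuplicated(fe$feature_id))
    stop("duplicate feature_id: ",
         fe$feature_id[duplicated(fe$feature_id)][1])
  if (!identical(rownames(counts), fe$feature_id))
    stop("matrix row names do not match feature_id order")
  bad <- which(!fe$feature_class %in% .FEATURE_CLASSES)
  if (length(bad))
    stop("unknown feature_class '", fe$feature_class[bad[1]],
         "' at feature '", fe$feature_id[bad[1]], "'")
  bad <- which(!fe$subgenome %in% .SUBGENOMES)
  if (length(bad))
    stop("unknown subgenome '", fe$subgenome[bad[1]],
         "' at feature '", fe$feature_id[bad[1]], "'")
  if (any(fe$order_index < 0, na.rm = TRUE))
    stop("order_index must be non-negative")
  if (any(!is.na(fe$length_bp) & fe$length_bp <= 0))
    stop("length_bp must be positive where present")
  gene <- fe$feature_class %in% c("hc_gene", "lc_gene")
  if (any(gene)) {
    key <- paste(fe$chromosome[gene], fe$order_index[gene])
    if (anyDuplicated(key))
      stop("duplicated (chromosome, order_index) among genes: ",
           key[duplicated(key)][1])
  }
  req_sa <- c("sample_id", "genotype_id", "tissue", "generation", "role",
              "replicate_of")
  miss <- setdiff(req_sa, names(sa))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(sa) != ncol(counts))
    stop("sample sheet has ", nrow(sa), " rows but matrix has ",
         ncol(counts), " columns")
  if (anyDuplicated(sa$sample_id))
    stop("duplicate sample_id: ", sa$sample_id[duplicated(sa$sample_id)][1])
  if (!identical(colnames(counts), sa$sample_id))
    stop("matrix column names do not match sample_id order")
  bad <- which(!sa$role %in% .SAMPLE_ROLES)
  if (length(bad))
    stop("unknown role '", sa$role[bad[1]], "' for sample '",
         sa$sample_id[bad[1]], "'")
  bad <- which(!sa$tissue %in% .TISSUES)
  if (length(bad))
    stop("unknown tissue '", sa$tissue[bad[1]], "' for sample '",
         sa$sample_id[bad[1]], "'")
  invisible(x)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d features x %d samples (unit = %s%s)\n",
              nrow(x$counts), ncol(x$counts), x$unit,
              if (x$corrected) ", mismatch-corrected" else ""))
  cat("feature classes:",
      paste(names(table(x$features$feature_class)),
            table(x$features$feature_class), collapse = ", "), "\n")
  cat("roles:",
      paste(names(table(x$samples$role)), table(x$samples$role),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Subset a count_table by features and/or samples
#'
#' @param x a [count_table()].
#' @param features,samples logical/integer indices or character ids; `NULL`
#'   keeps everything.
#' @return a [count_table()].
#' @export
subset_count_table <- function(x, features = NULL, samples = NULL) {
  fi <- .resolve_index(features, x$features$feature_id, "feature")
  si <- .resolve_index(samples, x$samples$sample_id, "sample")
  count_table(x$counts[fi, si, drop = FALSE],
              x$features[fi, , drop = FALSE],
              x$samples[si, , drop = FALSE],
              unit = x$unit, corrected = x$corrected)
}

.resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    m <- match(idx, ids)
    if (anyNA(idx <- m))
      stop("unknown ", what, " id(s) in subset")
    return(m)
  }
  idx
}

#' Load a dataset from TSV files
#'
#' Reads a raw count matrix (column `feature_id` plus one column per
#' sample), a feature annotation and a sample sheet, cross-validates them
#' and returns a [count_table()] with `unit = "counts"`.
#'
#' @param counts_path,annotation_path,samples_path TSV file paths.
#' @return a [count_table()].
#' @export
load_dataset <- function(counts_path, annotation_path, samples_path) {
  mat_df <- read.delim(counts_path, check.names = FALSE,
                       stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(mat_df))
    stop("count matrix lacks a 'feature_id' column")
  features <- read.delim(annotation_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  samples <- read.delim(samples_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  counts <- as.matrix(mat_df[, setdiff(names(mat_df), "feature_id"),
                             drop = FALSE])
  rownames(counts) <- mat_df$feature_id
  if (anyNA(counts))
    stop("count matrix contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at feature '", rownames(counts)[bad[1]],
         "', sample '", colnames(counts)[bad[2]], "'")
  }
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("raw count matrix contains non-integer values")
  miss <- setdiff(rownames(counts), features$feature_id)
  if (length(miss))
    stop("feature '", miss[1], "' missing from the annotation")
  miss <- setdiff(colnames(counts), samples$sample_id)
  if (length(miss))
    stop("sample '", miss[1], "' missing from the sample sheet")
  extra <- setdiff(samples$sample_id, colnames(counts))
  if (length(extra)) {
    warning("dropping ", length(extra),
            " sample sheet row(s) absent from the matrix")
    samples <- samples[samples$sample_id %in% colnames(counts), ,
                       drop = FALSE]
  }
  features <- features[match(rownames(counts), features$feature_id), ,
                       drop = FALSE]
  samples <- samples[match(colnames(counts), samples$sample_id), ,
                     drop = FALSE]
  if (is.null(samples$lib_size)) samples$lib_size <- colSums(counts)
  count_table(counts, features, samples, unit = "counts")
}

#' Read a homoeolog triad table
#'
#' @param path TSV with columns `triad_id`, `gene_A`, `gene_B`, `gene_D`.
#' @param features feature annotation data.frame used to verify that the
#'   three members exist and lie on subgenomes A, B and D respectively.
#' @return data.frame of triads.
#' @export
read_triad_table <- function(path, features = NULL) {
  tr <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_triad_table(tr, features)
  tr
}

#' Validate a triad table
#' @param triads data.frame with `triad_id`, `gene_A`, `gene_B`, `gene_D`.
#' @param features optional feature annotation for existence/subgenome
#'   checks.
#' @return `triads`, invisibly.
#' @export
validate_triad_table <- function(triads, features = NULL) {
  req <- c("triad_id", "gene_A", "gene_B", "gene_D")
  miss <- setdiff(req, names(triads))
  if (length(miss))
    stop("triad table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(triads$triad_id))
    stop("duplicate triad_id")
  same <- triads$gene_A == triads$gene_B | triads$gene_A == triads$gene_D |
    triads$gene_B == triads$gene_D
  if (any(same))
    stop("triad '", triads$triad_id[which(same)[1]],
         "' has non-distinct members")
  if (!is.null(features)) {
    for (sg in c("A", "B", "D")) {
      g <- triads[[paste0("gene_", sg)]]
      m <- match(g, features$feature_id)
      if (anyNA(m))
        stop("triad gene '", g[which(is.na(m))[1]],
             "' absent from the annotation")
      wrong <- which(features$subgenome[m] != sg)
      if (length(wrong))
        stop("triad gene '", g[wrong[1]], "' is not on subgenome ", sg)
    }
  }
  invisible(triads)
}

#' Write a result table to TSV
#'
#' Tab-separated, UTF-8, `NA` for missing values, no quoting, full numeric
#' precision (read-back agrees to at least 12 significant digits).
#'
#' @param table data.frame or matrix. Matrices are written with a leading
#'   `feature_id` column taken from row names.
#' @param path output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  if (is.matrix(table)) {
    table <- data.frame(feature_id = rownames(table),
                        as.data.frame(table, check.names = FALSE),
                        check.names = FALSE)
  }
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  table[] <- lapply(table, function(col) {
    if (is.numeric(col)) col[is.nan(col)] <- NA
    col
  })
  write.table(format(table, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a count_table as a trio of TSV files
#'
#' @param x a [count_table()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
write_count_table <- function(x, dir, prefix = "dataset") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, paste0(prefix, "_counts.tsv")),
    features = file.path(dir, paste0(prefix, "_features.tsv")),
    samples = file.path(dir, paste0(prefix, "_samples.tsv")))
  write_table(x$counts, paths["counts"])
  write_table(x$features, paths["features"])
  write_table(x$samples, paths["samples"])
  invisible(paths)
}
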