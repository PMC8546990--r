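## Two-kingdom OTU count tables and the tabular I/O dialect.
## Orientation is rows = OTUs, columns = samples throughout.

#' Construct a two-kingdom OTU count table
#'
#' An `otu_table` holds a non-negative integer count matrix (rows = OTUs,
#' columns = samples) together with a per-OTU kingdom label
#' (`"bacteria"` or `"fungi"`). OTU and sample identifiers must be unique.
#' Zero-sample tables are permitted (e.g. a simulation with `n_samples = 0`);
#' zero-OTU tables are not.
#'
#' @param counts Integer matrix with unique rownames (OTU ids) and unique
#'   colnames (sample ids). Values must be non-negative whole numbers.
#' @param kingdom Character vector of kingdom labels, either named by OTU id
#'   or in row order of `counts`; a single value is recycled.
#' @return An object of class `otu_table` with elements `counts` and
#'   `kingdom` (named by OTU id).
#' @export
otu_table <- function(counts, kingdom) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L) {
    stop("otu_table needs at least one OTU row")
  }
  if (is.null(rownames(counts))) {
    stop("counts must have OTU ids as rownames")
  }
  if (ncol(counts) > 0L && is.null(colnames(counts))) {
    stop("counts must have sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (ncol(counts) > 0L && anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (anyNA(counts) || !is.numeric(counts)) {
    stop("counts must be numeric and complete")
  }
  if (any(counts < 0)) {
    stop("negative counts are not allowed")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be whole numbers")
  }
  storage.mode(counts) <- "integer"

  if (length(kingdom) == 1L) kingdom <- rep(kingdom, nrow(counts))
  if (!is.null(names(kingdom))) {
    missing <- setdiff(rownames(counts), names(kingdom))
    if (length(missing)) {
      stop("OTUs without a kingdom label: ", paste(head(missing, 5L), collapse = ", "))
    }
    kingdom <- kingdom[rownames(counts)]
  } else if (length(kingdom) != nrow(counts)) {
    stop("kingdom must have one label per OTU")
  }
  kingdom <- as.character(kingdom)
  bad <- setdiff(unique(kingdom), .kingdoms)
  if (length(bad)) {
    stop("unknown kingdom label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.kingdoms, collapse = "/"), ")")
  }
  names(kingdom) <- rownames(counts)

  structure(list(counts = counts, kingdom = kingdom), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (%d bacterial, %d fungal)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$kingdom == "bacteria"), sum(x$kingdom == "fungi")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' OTU and sample identifiers
#'
#' @param x An `otu_table` or `rel_abundance_table`.
#' @return Character vector of ids.
#' @export
otu_ids <- function(x) rownames(.values(x))

#' @rdname otu_ids
#' @export
sample_ids <- function(x) colnames(.values(x))

## Internal: numeric matrix behind either table class.
.values <- function(x) {
  if (inherits(x, "otu_table")) return(x$counts)
  if (inherits(x, "rel_abundance_table")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected an otu_table, rel_abundance_table, or matrix")
}

#' Subset an OTU table
#'
#' @param x An `otu_table`.
#' @param otus,samples Index vectors (ids, positions, or logical) selecting
#'   rows/columns; `NULL` keeps all.
#' @return An `otu_table`.
#' @export
subset_table <- function(x, otus = NULL, samples = NULL) {
  stopifnot(inherits(x, "otu_table"))
  counts <- x$counts
  if (!is.null(otus)) counts <- counts[otus, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  otu_table(counts, x$kingdom[rownames(counts)])
}

#' Read an OTU table and its taxonomy map
#'
#' Reads a tab-separated count table (first column OTU id, header row of
#' sample ids) plus a two-column taxonomy file mapping `otu_id` to `kingdom`.
#' OTUs present in the counts but absent from the taxonomy are an error.
#'
#' @param path Path to the count TSV.
#' @param taxonomy_path Path to the taxonomy TSV (columns `otu_id`, `kingdom`).
#' @return An `otu_table`.
#' @export
read_otu_table <- function(path, taxonomy_path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 1L) stop("empty OTU table: ", path)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate OTU ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  snames <- colnames(raw)[-1L]
  if (anyDuplicated(snames)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(snames[duplicated(snames)]), collapse = ", "))
  }
  counts <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric counts in ", path)
  rownames(counts) <- ids

  tax <- read.delim(taxonomy_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("otu_id", "kingdom") %in% colnames(tax))) {
    stop("taxonomy file must have columns otu_id and kingdom: ", taxonomy_path)
  }
  missing <- setdiff(ids, tax$otu_id)
  if (length(missing)) {
    stop("OTUs missing from taxonomy: ", paste(head(missing, 5L), collapse = ", "))
  }
  kingdom <- setNames(as.character(tax$kingdom), tax$otu_id)[ids]
  otu_table(counts, kingdom)
}

#' Write an OTU table (and optionally its taxonomy) as TSV
#'
#' Canonical dialect: UTF-8, tab-separated, `.` decimal, no quoting, counts as
#' plain integers. `write_otu_table(read_otu_table(...))` is byte-identical
#' for files in this dialect.
#'
#' @param x An `otu_table`.
#' @param path Output path for the count TSV.
#' @param taxonomy_path Optional output path for the taxonomy TSV.
#' @param id_column Name of the first (OTU id) column. Default `"otu_id"`.
#' @return Invisibly, `x`.
#' @export
write_otu_table <- function(x, path, taxonomy_path = NULL, id_column = "otu_id") {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(otu_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  if (!is.null(taxonomy_path)) {
    tax <- data.frame(otu_id = names(x$kingdom), kingdom = unname(x$kingdom),
                      stringsAsFactors = FALSE)
    write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(x)
}

#' Read per-sample metadata
#'
#' Required columns: `sample_id`, `habitat`, `layer`, `site`, `pH`,
#' `moisture`, and the eight nutrient variables (see [nutrient_vars()]).
#' Extra columns are preserved. Missing nutrient values are encoded `NA` and
#' flagged with a warning (they exclude the sample from the MNC only).
#'
#' @param path Path to the TSV.
#' @param habitats,layers Allowed vocabularies for the `habitat` and `layer`
#'   columns.
#' @return A `data.frame` with one row per sample.
#' @export
read_sample_frame <- function(path, habitats = .default_habitats,
                              layers = .layers) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  required <- c("sample_id", "habitat", "layer", "site", "pH", "moisture",
                nutrient_vars())
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("sample frame missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id values in ", path)
  bad_h <- setdiff(unique(df$habitat), habitats)
  if (length(bad_h)) stop("unknown habitat value(s): ", paste(bad_h, collapse = ", "))
  bad_l <- setdiff(unique(df$layer), layers)
  if (length(bad_l)) stop("unknown layer value(s): ", paste(bad_l, collapse = ", "))
  for (col in c("pH", "moisture", nutrient_vars())) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (any(is.na(conv) & !is.na(v) & v != "NA")) {
        stop("unparseable numeric value(s) in column ", col)
      }
      df[[col]] <- conv
    }
  }
  n_missing <- sum(!complete.cases(df[, nutrient_vars()]))
  if (n_missing > 0L) {
    warning(n_missing, " sample(s) have missing nutrient values; ",
            "they will be excluded from the MNC")
  }
  df
}

#' Write per-sample metadata as TSV
#'
#' @param df Sample frame as returned by [read_sample_frame()].
#' @param path Output path.
#' @return Invisibly, `df`.
#' @export
write_sample_frame <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(df)
}

#' Stack bacterial and fungal OTU tables into one two-kingdom table
#'
#' The inputs must cover the same samples (order may differ; the bacterial
#' order wins). OTU id clashes between the kingdoms are resolved by prefixing
#' the clashing ids with `"bacteria|"` / `"fungi|"`. Column sums are conserved:
#' each merged sample total equals the sum of the two input totals.
#'
#' @param bacteria,fungi `otu_table` objects with kingdoms `"bacteria"` and
#'   `"fungi"` respectively.
#' @return An `otu_table` holding both kingdoms.
#' @export
merge_kingdom_tables <- function(bacteria, fungi) {
  stopifnot(inherits(bacteria, "otu_table"), inherits(fungi, "otu_table"))
  sb <- sample_ids(bacteria)
  sf <- sample_ids(fungi)
  if (!setequal(sb, sf)) {
    only_b <- setdiff(sb, sf)
    only_f <- setdiff(sf, sb)
    stop("sample sets differ; only in bacteria: ",
         paste(only_b, collapse = ", "), "; only in fungi: ",
         paste(only_f, collapse = ", "))
  }
  cb <- bacteria$counts
  cf <- fungi$counts[, sb, drop = FALSE]
  clash <- intersect(rownames(cb), rownames(cf))
  if (length(clash)) {
    rownames(cb)[rownames(cb) %in% clash] <-
      paste0("bacteria|", rownames(cb)[rownames(cb) %in% clash])
    rownames(cf)[rownames(cf) %in% clash] <-
      paste0("fungi|", rownames(cf)[rownames(cf) %in% clash])
  }
  counts <- rbind(cb, cf)
  kingdom <- setNames(c(rep("bacteria", nrow(cb)), rep("fungi", nrow(cf))),
                      rownames(counts))
  otu_table(counts, kingdom)
}

#' Read an association-count table with printed (comma-grouped) integers
#'
#' Reads a TSV of kingdom-partitioned association counts in which the integer
#' columns may use thousands separators as printed in publication tables
#' (e.g. `26,626`). Commas are stripped before parsing.
#'
#' @param path Path to the TSV with columns `habitat`, `layer`, `partition`,
#'   `neg`, `pos`, and optionally `pro_printed`.
#' @return A `data.frame` with integer `neg`/`pos`.
#' @export
read_association_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  required <- c("habitat", "layer", "partition", "neg", "pos")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("association count table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  strip <- function(v) as.numeric(gsub(",", "", v, fixed = TRUE))
  df$neg <- strip(df$neg)
  df$pos <- strip(df$pos)
  if ("pro_printed" %in% colnames(df)) df$pro_printed <- as.numeric(df$pro_printed)
  if (anyNA(df$neg) || anyNA(df$pos)) stop("unparseable count in ", path)
  df
}
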