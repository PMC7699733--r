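#' Read a protein quantification table
#'
#' Reads a tab-delimited protein-level quantification table in the MaxQuant
#' proteinGroups dialect: one row per protein group, an identifier column,
#' a gene-symbol column, per-sample intensity columns sharing a common
#' prefix (default `"iBAQ "`), and optional "+"-flag columns marking
#' reverse-database hits and common contaminants.  Flagged rows are kept in
#' the returned matrix but marked for removal by [remove_contaminants()].
#'
#' Blank or missing intensities are coerced to 0 ("not identified");
#' anything else non-numeric is a format error naming the offending row and
#' column.
#'
#' @param path path to the tab-delimited file (with a header line; lines
#'   starting with `#` are treated as comments).
#' @param id_column name of the protein/isoform accession column.
#' @param gene_column name of the gene-symbol column; if absent, symbols
#'   default to the protein id.
#' @param ibaq_prefix common prefix of the per-sample intensity columns;
#'   sample ids are the column names with the prefix stripped.
#' @param reverse_column,contaminant_column names of the "+"-flag columns;
#'   either may be absent from the file.
#' @return A [quant_matrix()].
#' @export
read_quant_table <- function(path, id_column = "Protein IDs",
                             gene_column = "Gene names",
                             ibaq_prefix = "iBAQ ",
                             reverse_column = "Reverse",
                             contaminant_column = "Potential contaminant") {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!id_column %in% names(df))
    stop("format error: id column '", id_column, "' not found in ", path,
         call. = FALSE)
  ibaq_cols <- names(df)[startsWith(names(df), ibaq_prefix)]
  if (!length(ibaq_cols))
    stop("format error: no columns with prefix '", ibaq_prefix, "' in ",
         path, call. = FALSE)
  ids <- df[[id_column]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("format error: duplicate protein ids: ",
         paste(dup, collapse = ", "), call. = FALSE)

  vals <- matrix(0, nrow(df), length(ibaq_cols))
  for (k in seq_along(ibaq_cols)) {
    raw <- trimws(df[[ibaq_cols[k]]])
    raw[raw == "" | is.na(raw) | raw == "NA" | raw == "NaN"] <- "0"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num))
    if (length(bad))
      stop("format error: non-numeric intensity '", raw[bad[1]],
           "' at row ", bad[1], ", column '", ibaq_cols[k], "'",
           call. = FALSE)
    vals[, k] <- num
  }

  genes <- if (gene_column %in% names(df)) {
    g <- df[[gene_column]]
    ifelse(is.na(g) | g == "", ids, g)
  } else ids

  plus_flag <- function(col) {
    if (col %in% names(df)) !is.na(df[[col]]) & trimws(df[[col]]) == "+"
    else rep(FALSE, nrow(df))
  }
  flagged <- plus_flag(reverse_column) | plus_flag(contaminant_column)

  quant_matrix(vals, protein_ids = ids, gene_symbols = genes,
               sample_ids = sub(ibaq_prefix, "", ibaq_cols, fixed = TRUE),
               flagged = flagged)
}

#' Write a quant_matrix as a tab-delimited table
#'
#' Inverse of [read_quant_table()]: the written file round-trips through the
#' reader with values and identifiers preserved to full precision.
#'
#' @param m a `quant_matrix`.
#' @param path output path.
#' @param ibaq_prefix prefix prepended to sample ids to form intensity
#'   column names.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(m, path, ibaq_prefix = "iBAQ ") {
  stopifnot(inherits(m, "quant_matrix"))
  df <- data.frame(`Protein IDs` = m$protein_ids,
                   `Gene names` = m$gene_symbols,
                   Reverse = "",
                   `Potential contaminant` = ifelse(m$flagged, "+", ""),
                   check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.data.frame(m$values)
  names(v) <- paste0(ibaq_prefix, m$sample_ids)
  df <- cbind(df, format(v, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads the per-sample clinical/technical annotation table (CSV) used
#' throughout the pipeline: cancer status, gender, smoking history,
#' experimental batch, stage, vital status and age group.
#'
#' @param path CSV path with at least a `sample_id` column.
#' @return A data.frame with one row per sample, factor columns for the
#'   clinical variables, and class `c("sample_metadata", "data.frame")`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_sample_metadata(df)
}

#' Validate a sample-metadata data.frame
#'
#' @param df a data.frame with a unique `sample_id` column and any of the
#'   standard clinical columns (`cancer_status`, `gender`, `smoking`,
#'   `batch`, `stage`, `vital_status`, `age_group`).
#' @return The validated data.frame with class `sample_metadata` prepended.
#' @export
as_sample_metadata <- function(df) {
  if (!"sample_id" %in% names(df))
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  levelled <- list(
    cancer_status = c("NO", "YES"),
    gender = c("F", "M", "NA"),
    smoking = c("current", "former", "non", "unknown"),
    stage = c("no", "2", "3", "4", "NA"),
    vital_status = c("alive", "dead"),
    age_group = c("<55", ">55", "NA")
  )
  for (col in intersect(names(levelled), names(df))) {
    x <- as.character(df[[col]])
    x[is.na(x)] <- "NA"
    bad <- setdiff(unique(x), levelled[[col]])
    if (length(bad))
      stop("metadata column '", col, "' has unexpected level(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    df[[col]] <- factor(x, levels = levelled[[col]])
    df[[col]] <- droplevels(df[[col]])
  }
  if ("batch" %in% names(df)) df$batch <- factor(df$batch)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

# align metadata rows with the columns of a quant_matrix
align_metadata <- function(m, meta) {
  missing <- setdiff(m$sample_ids, meta$sample_id)
  if (length(missing))
    stop("samples absent from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta[match(m$sample_ids, meta$sample_id), , drop = FALSE]
}

#' Read a gene-set collection (GMT)
#'
#' Standard GMT dialect: one set per line, tab-delimited, fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.  Duplicate members
#' within a line are removed with a warning.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (class `gene_set_collection`);
#'   each element carries its description in attribute `"description"`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("format error: GMT line ", i, " has fewer than 3 fields",
           call. = FALSE)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[1], "' deduplicated",
              call. = FALSE)
      members <- unique(members)
    }
    sets[[f[1]]] <- structure(members, description = f[2])
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors (as from [read_gene_sets()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a nanoparticle-tracking size distribution
#'
#' Reads a CSV export of particle counts per size bin.  The pipeline works
#' on a uniform 0.5 nm grid; input on a finer uniform grid is rebinned by
#' summing counts into 0.5 nm bins.
#'
#' @param path CSV with columns `size` (bin left edge, nm) and `count`.
#' @param sample_id identifier attached to the distribution; defaults to the
#'   file name without extension.
#' @return A data.frame (class `size_distribution`) with columns `size`
#'   (ascending, uniform 0.5 nm spacing) and `count`, plus attribute
#'   `sample_id`.
#' @export
read_size_distribution <- function(path, sample_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("size", "count") %in% names(df)))
    stop("format error: size-distribution CSV needs 'size' and 'count' ",
         "columns (", path, ")", call. = FALSE)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  as_size_distribution(df$size, df$count, sample_id)
}

#' Construct / validate a size distribution on the 0.5 nm grid
#'
#' @param size numeric vector of ascending bin left edges in nm.
#' @param count non-negative particle counts per bin.
#' @param sample_id identifier for the sample.
#' @return A `size_distribution` data.frame (see [read_size_distribution()]).
#' @export
as_size_distribution <- function(size, count, sample_id) {
  if (length(size) != length(count))
    stop("size and count lengths differ", call. = FALSE)
  o <- order(size)
  size <- size[o]; count <- count[o]
  bad <- which(count < 0)
  if (length(bad))
    stop("format error: negative count at size ", size[bad[1]], " nm",
         call. = FALSE)
  steps <- diff(size)
  if (length(steps) && !isTRUE(all.equal(steps, rep(steps[1], length(steps)),
                                         tolerance = 1e-8)))
    stop("format error: non-uniform bin spacing", call. = FALSE)
  step <- if (length(steps)) steps[1] else 0.5
  if (!isTRUE(all.equal(step, 0.5, tolerance = 1e-8))) {
    if (step > 0.5 + 1e-8)
      stop("format error: bin spacing ", step,
           " nm is coarser than the 0.5 nm grid", call. = FALSE)
    # rebin a finer uniform grid by summing counts into 0.5 nm bins
    edge <- floor(size / 0.5) * 0.5
    agg <- rowsum(count, group = edge, reorder = TRUE)
    size <- as.numeric(rownames(agg))
    count <- as.numeric(agg)
  }
  structure(data.frame(size = size, count = count),
            sample_id = as.character(sample_id),
            class = c("size_distribution", "data.frame"))
}

#' Write a size distribution to CSV
#'
#' @param d a `size_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_size_distribution <- function(d, path) {
  utils::write.csv(data.frame(size = d$size, count = d$count), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read marker panels from YAML
#'
#' A marker panel maps named cell populations or subcellular compartments to
#' marker gene symbols, and flags each marker as an extracellular-vesicle
#' (EV) marker, a non-EV contamination marker (organelle proteins such as
#' BCL2, GOLGA2, NUP98, CANX), or a cell-population marker.
#'
#' Expected YAML layout:
#' ```
#' ev_markers: [CD63, CD9, ...]
#' non_ev_markers: [BCL2, GOLGA2, NUP98, CANX]
#' populations:
#'   T cells: [CD3D, CD3G, ...]
#'   ...
#' ```
#'
#' @param path YAML file path.
#' @return A `marker_panel`: list with `panels` (named list of symbol
#'   vectors, including `EV` and `non-EV`) and `flags` (named character
#'   vector marker -> one of `"EV"`, `"non-EV"`, `"cell-population"`).
#' @export
read_marker_panels <- function(path) {
  y <- yaml::read_yaml(path)
  marker_panel(ev = as.character(y$ev_markers),
               non_ev = as.character(y$non_ev_markers),
               populations = lapply(y$populations, as.character))
}

#' Construct a marker panel
#'
#' @param ev character vector of EV marker symbols.
#' @param non_ev character vector of non-EV (contamination) marker symbols.
#' @param populations named list of cell-population marker vectors.
#' @return A `marker_panel` object; see [read_marker_panels()].
#' @export
marker_panel <- function(ev = character(), non_ev = character(),
                         populations = list()) {
  panels <- c(list(EV = unique(ev), `non-EV` = unique(non_ev)),
              lapply(populations, unique))
  flags <- c(stats::setNames(rep("EV", length(unique(ev))), unique(ev)),
             stats::setNames(rep("non-EV", length(unique(non_ev))),
                             unique(non_ev)))
  pop_markers <- unique(unlist(populations, use.names = FALSE))
  pop_markers <- setdiff(pop_markers, names(flags))
  flags <- c(flags, stats::setNames(rep("cell-population",
                                        length(pop_markers)), pop_markers))
  overlap <- intersect(unique(ev), unique(non_ev))
  if (length(overlap))
    stop("marker(s) flagged both EV and non-EV: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  structure(list(panels = panels, flags = flags), class = "marker_panel")
}

#' Write marker panels to YAML
#'
#' @param panel a `marker_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_panels <- function(panel, path) {
  pops <- panel$panels[setdiff(names(panel$panels), c("EV", "non-EV"))]
  yaml::write_yaml(list(ev_markers = panel$panels$EV,
                        non_ev_markers = panel$panels$`non-EV`,
                        populations = pops), path)
  invisible(path)
}
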