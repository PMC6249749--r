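# On-disk formats. Sample tables and species matrices are plain TSV/CSV;
# the delimiter is inferred from the file extension (.csv -> comma,
# anything else -> tab), text is UTF-8, decimal point is ".".

.delimFor <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a sample-level count table
#'
#' Reads a delimited file whose first three columns are `sample_id`,
#' `forest_id` and `plant_label`, followed by one integer read-count column
#' per fungal OTU. Row and column order is preserved from the file.
#'
#' @param path Path to a `.tsv` or `.csv` file.
#' @param forest Optional forest id to select when the file holds several
#'   forests; with the default `NULL` the file must contain exactly one.
#' @return A [SampleTable].
#' @seealso [writeSampleTable()]
#' @export
readSampleTable <- function(path, forest = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.table(path, header = TRUE, sep = .delimFor(path), quote = "",
                  check.names = FALSE, stringsAsFactors = FALSE,
                  comment.char = "", fileEncoding = "UTF-8")
  req <- c("sample_id", "forest_id", "plant_label")
  if (!all(req %in% names(d)))
    stop("format error: missing required column(s): ",
         paste(setdiff(req, names(d)), collapse = ", "), call. = FALSE)
  if (ncol(d) <= length(req))
    stop("format error: no OTU count columns found", call. = FALSE)
  if (!is.null(forest)) {
    d <- d[d$forest_id == forest, , drop = FALSE]
    if (nrow(d) == 0L) stop("no samples for forest '", forest, "'", call. = FALSE)
  }
  forests <- unique(d$forest_id)
  if (length(forests) != 1L)
    stop("file contains several forests (", paste(forests, collapse = ", "),
         "); use the 'forest' argument to pick one", call. = FALSE)
  cn <- setdiff(names(d), req)
  counts <- as.matrix(d[, cn, drop = FALSE])
  if (!is.numeric(counts)) {
    bad <- cn[!vapply(d[cn], is.numeric, logical(1))][1L]
    stop("validation error: non-numeric count in column '", bad, "'",
         call. = FALSE)
  }
  rownames(counts) <- as.character(d$sample_id)
  msg <- .checkCountMatrix(counts)
  if (!is.null(msg)) stop("validation error: ", msg, call. = FALSE)
  SampleTable(counts, as.character(d$plant_label), forests)
}

#' Write a sample-level count table
#'
#' @param x A [SampleTable].
#' @param path Output path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
writeSampleTable <- function(x, path) {
  stopifnot(is(x, "SampleTable"))
  d <- data.frame(
    sample_id = sampleIds(x),
    forest_id = forestId(x),
    plant_label = plantLabels(x),
    countMatrix(x),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(d, path, sep = .delimFor(path), quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# FUNGuild-style guild strings are mapped onto the closed five-value
# vocabulary with precedence ECM > AM > PATHO > SAPENDO, so that combined
# annotations ("Ectomycorrhizal-Saprotroph") resolve to a single exclusive
# guild and saprotroph-endophyte combinations pool into SAPENDO.
.mapGuild <- function(x) {
  x <- as.character(x)
  out <- character(length(x))
  for (i in seq_along(x)) {
    raw <- trimws(x[i])
    if (is.na(raw) || !nzchar(raw) ||
        toupper(raw) %in% c("UNKNOWN", "UNASSIGNED", "NA", "NULL")) {
      out[i] <- "UNKNOWN"
    } else if (toupper(raw) %in% .GUILDS) {
      out[i] <- toupper(raw)
    } else {
      low <- tolower(raw)
      out[i] <-
        if (grepl("ectomycorrhiz", low)) "ECM"
        else if (grepl("arbuscular", low)) "AM"
        else if (grepl("pathogen", low)) "PATHO"
        else if (grepl("saprotroph|endophyt", low)) "SAPENDO"
        else stop("validation error: unrecognized guild value '", raw, "'",
                  call. = FALSE)
    }
  }
  out
}

.mapPlantType <- function(x) {
  x <- as.character(x)
  out <- character(length(x))
  for (i in seq_along(x)) {
    raw <- trimws(x[i])
    if (is.na(raw) || !nzchar(raw)) {
      warning("blank mycorrhizal_type treated as NM_PLANT", call. = FALSE)
      out[i] <- "NM_PLANT"
    } else if (toupper(raw) %in% .PLANT_TYPES) {
      out[i] <- toupper(raw)
    } else {
      low <- tolower(raw)
      out[i] <-
        if (grepl("dual|both", low)) "DUAL"
        else if (grepl("non.?mycorrhiz", low)) "NM_PLANT"
        else if (grepl("ectomycorrhiz", low)) "ECM_PLANT"
        else if (grepl("arbuscular", low)) "AM_PLANT"
        else stop("validation error: unrecognized mycorrhizal_type '", raw,
                  "'", call. = FALSE)
    }
  }
  out
}

#' Read OTU or plant annotations
#'
#' OTU annotations are a delimited table with columns `otu_id`, optionally
#' `taxonomy`, and `guild`; plant annotations have columns `plant_label` and
#' `mycorrhizal_type`. Guild strings in the style of functional-guild
#' databases (e.g. "Arbuscular Mycorrhizal", "Ectomycorrhizal-Saprotroph")
#' are mapped onto the closed vocabulary `fungalGuilds()` with precedence
#' ECM > AM > PATHO > SAPENDO; blank or unknown guilds become `UNKNOWN`.
#'
#' @param path Path to a `.tsv` or `.csv` file.
#' @param kind `"otu"` or `"plant"`.
#' @return A data.frame with canonical columns (`otu_id`, `taxonomy`,
#'   `guild`) or (`plant_label`, `mycorrhizal_type`).
#' @export
readAnnotations <- function(path, kind = c("otu", "plant")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.table(path, header = TRUE, sep = .delimFor(path), quote = "",
                  check.names = FALSE, stringsAsFactors = FALSE,
                  comment.char = "", fileEncoding = "UTF-8",
                  colClasses = "character", na.strings = NULL)
  if (kind == "otu") {
    if (!all(c("otu_id", "guild") %in% names(d)))
      stop("format error: OTU annotations need columns otu_id and guild",
           call. = FALSE)
    if (anyDuplicated(d$otu_id))
      stop("validation error: duplicated otu_id: ",
           d$otu_id[duplicated(d$otu_id)][1L], call. = FALSE)
    data.frame(
      otu_id = d$otu_id,
      taxonomy = if ("taxonomy" %in% names(d)) d$taxonomy else NA_character_,
      guild = .mapGuild(d$guild),
      stringsAsFactors = FALSE
    )
  } else {
    if (!all(c("plant_label", "mycorrhizal_type") %in% names(d)))
      stop("format error: plant annotations need columns plant_label and ",
           "mycorrhizal_type", call. = FALSE)
    if (anyDuplicated(d$plant_label))
      stop("validation error: duplicated plant_label: ",
           d$plant_label[duplicated(d$plant_label)][1L], call. = FALSE)
    data.frame(
      plant_label = d$plant_label,
      mycorrhizal_type = .mapPlantType(d$mycorrhizal_type),
      stringsAsFactors = FALSE
    )
  }
}

#' @rdname readAnnotations
#' @param ann An annotation data.frame as returned by [readAnnotations()].
#' @export
writeAnnotations <- function(ann, path, kind = c("otu", "plant")) {
  kind <- match.arg(kind)
  req <- if (kind == "otu") c("otu_id", "guild") else
    c("plant_label", "mycorrhizal_type")
  stopifnot(all(req %in% names(ann)))
  write.table(ann, path, sep = .delimFor(path), quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write a species-level association matrix
#'
#' Species matrices are stored as TSV with plants as rows (first column
#' `plant_label`) and OTUs as columns, preceded by header comment lines
#' carrying the network category and forest id.
#'
#' @param x A [SpeciesMatrix].
#' @param path Output (input) path.
#' @return `writeSpeciesMatrix` returns `path` invisibly;
#'   `readSpeciesMatrix` returns a [SpeciesMatrix].
#' @export
writeSpeciesMatrix <- function(x, path) {
  stopifnot(is(x, "SpeciesMatrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# category: %s", networkCategory(x)),
               sprintf("# forest: %s", forestId(x))), con)
  d <- data.frame(plant_label = plantLabels(x), assocMatrix(x),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpeciesMatrix
#' @export
readSpeciesMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 10L, encoding = "UTF-8")
  hdr <- hdr[startsWith(hdr, "#")]
  pick <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) stop("format error: missing '# ", key, ":' header",
                          call. = FALSE)
    trimws(sub(sprintf("^# %s:", key), "", ln[1L]))
  }
  d <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  check.names = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#", fileEncoding = "UTF-8")
  assoc <- as.matrix(d[, setdiff(names(d), "plant_label"), drop = FALSE])
  rownames(assoc) <- d$plant_label
  SpeciesMatrix(assoc, pick("category"), pick("forest"), prune = FALSE)
}

#' Write (and read back) an analysis results bundle
#'
#' Writes the property table as `results.tsv` and the provenance record
#' (seeds, permutation counts, thresholds) as `results.json` in `dir`. The
#' provenance record must carry at least `seed` and `n_perm`; a bundle
#' without them is refused, so that written results are always reproducible.
#'
#' @param bundle A list with elements `property_table` (data.frame, see
#'   [buildPropertyTable()]) and `provenance` (named list with at least
#'   `seed` and `n_perm`). Further elements are carried into the JSON.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeResults <- function(bundle, dir) {
  if (!is.list(bundle) || is.null(bundle$property_table) ||
      is.null(bundle$provenance))
    stop("bundle must be a list with elements property_table and provenance",
         call. = FALSE)
  prov <- bundle$provenance
  if (is.null(prov$seed) || is.null(prov$n_perm))
    stop("provenance must record 'seed' and 'n_perm'; refusing to write ",
         "results without reproducibility metadata", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(bundle$property_table, file.path(dir, "results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  jsonlite::write_json(bundle[setdiff(names(bundle), "property_table")],
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeResults
#' @export
readResults <- function(dir) {
  pt <- read.table(file.path(dir, "results.tsv"), header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  meta <- jsonlite::read_json(file.path(dir, "results.json"),
                              simplifyVector = TRUE)
  c(list(property_table = pt), meta)
}
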