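#' Read NanoString RCC lane files
#'
#' Parses the per-lane text container emitted by the instrument: tagged
#' sections (`<Header>`, `<Sample_Attributes>`, `<Lane_Attributes>`,
#' `<Code_Summary>`) of comma-separated lines. Unknown sections are skipped;
#' each file contributes one sample. The sample id is taken from the `ID`
#' field of `Sample_Attributes` when present, else the file stem.
#'
#' @param paths character vector of RCC file paths, one lane each.
#' @return a raw-stage [count_matrix()]; sample order follows `paths`.
#' @export
read_rcc <- function(paths) {
  if (!length(paths)) stop("no RCC files given")
  one <- function(path) {
    lines <- readLines(path, warn = FALSE)
    sec <- NULL
    sections <- list()
    for (ln in lines) {
      ln <- trimws(ln)
      if (ln == "") next
      m <- regmatches(ln, regexec("^<(/?)([A-Za-z_]+)>$", ln))[[1]]
      if (length(m) == 3) {
        sec <- if (m[2] == "/") NULL else m[3]
        if (!is.null(sec) && is.null(sections[[sec]])) sections[[sec]] <- character()
        next
      }
      if (!is.null(sec)) sections[[sec]] <- c(sections[[sec]], ln)
    }
    if (is.null(sections$Code_Summary)) {
      stop("RCC file has no Code_Summary section: ", path)
    }
    body <- utils::read.csv(text = paste(sections$Code_Summary, collapse = "\n"),
                            stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("CodeClass", "Name", "Count")
    if (!all(need %in% names(body))) {
      stop("Code_Summary lacks columns ", paste(setdiff(need, names(body)),
                                                collapse = ", "), ": ", path)
    }
    sid <- NULL
    if (!is.null(sections$Sample_Attributes)) {
      attrs <- strsplit(sections$Sample_Attributes, ",")
      ids <- vapply(attrs, `[`, "", 1)
      if ("ID" %in% ids) {
        v <- attrs[[match("ID", ids)]]
        if (length(v) >= 2 && nzchar(v[2])) sid <- v[2]
      }
    }
    if (is.null(sid)) sid <- sub("\\.[Rr][Cc][Cc]$", "", basename(path))
    list(sid = sid, body = body)
  }
  parsed <- lapply(paths, one)
  ref <- parsed[[1]]$body$Name
  for (p in parsed[-1]) {
    if (!identical(sort(p$body$Name), sort(ref))) {
      bad <- union(setdiff(ref, p$body$Name), setdiff(p$body$Name, ref))
      stop("probe sets differ across RCC files; offending probes: ",
           paste(sort_genes(bad), collapse = ", "))
    }
  }
  counts <- vapply(parsed, function(p) {
    p$body$Count[match(ref, p$body$Name)]
  }, numeric(length(ref)))
  counts <- matrix(as.numeric(counts), nrow = length(ref),
                   dimnames = list(ref, vapply(parsed, `[[`, "", "sid")))
  class_map <- c(endogenous = "endogenous", housekeeping = "housekeeping",
                 positive = "positive", negative = "negative")
  cls <- class_map[tolower(parsed[[1]]$body$CodeClass)]
  cls[is.na(cls)] <- parsed[[1]]$body$CodeClass[is.na(cls)]
  probes <- probe_def(ref, cls)
  count_matrix(counts, probes, stage = "raw")
}

#' Read a genes x samples count matrix from CSV
#'
#' First column gene ids, remaining columns one per sample. The stage of the
#' data (raw vs already normalized) is declared by the caller, since exported
#' matrices do not record it.
#'
#' @param path CSV file path.
#' @param codeset code-set table from [probe_def()] or [read_codeset_csv()].
#'   Gene ids in the file but not in the code set are an error naming them.
#' @param stage declared stage of the stored values.
#' @return a [count_matrix()].
#' @export
read_counts_csv <- function(path, codeset, stage = "raw") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric count body in ", path)
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts in ", path)
  storage.mode(counts) <- "double"
  rownames(counts) <- genes
  count_matrix(counts, codeset, stage = stage)
}

#' Write a count matrix to CSV
#'
#' @param cm a [count_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a code-set table (gene_id, probe_class, note)
#'
#' @param path CSV path.
#' @return [read_codeset_csv()] returns a validated code-set `data.frame`.
#' @export
read_codeset_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "probe_class") %in% names(df))) {
    stop("code-set CSV needs gene_id and probe_class columns: ", path)
  }
  probe_def(df$gene_id, df$probe_class, df$note %||% "")
}

#' @rdname read_codeset_csv
#' @param probes code-set table.
#' @export
write_codeset_csv <- function(probes, path) {
  utils::write.csv(probes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' Expected columns: `sample_id`, `group`, and optionally `igvh_status`,
#' `pct_cd38_pos`, `pct_malignant`, `zap70_status`. Enum columns are
#' case-insensitive; missing optional columns are filled with
#' unknown/missing.
#'
#' @param path CSV path.
#' @return validated sample-sheet `data.frame` (see [sample_sheet()]).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("sample sheet needs sample_id and group columns: ", path)
  }
  sample_sheet(df$sample_id, df$group,
               igvh_status = df$igvh_status %||% "unknown",
               pct_cd38_pos = df$pct_cd38_pos %||% NA_real_,
               pct_malignant = df$pct_malignant %||% NA_real_,
               zap70_status = df$zap70_status %||% "unknown")
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet `data.frame`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
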