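#' Read a curated interaction database
#'
#' Accepts the multi-sheet workbook layout used by curated AGE-interaction
#' databases (sheets `ages`, `receptors`, an interaction sheet such as
#' `AGE-TRPV1`, `analysis`, `reference`, recognized case-insensitively), or a
#' plain CSV/TSV edge list, or a SIF file. The interaction sheet's column
#' layout is sniffed: columns named `source`/`target` (plus optional
#' `interaction_type` and `provenance`) are used when present, otherwise the
#' first three columns are taken in SIF order (source, interaction type,
#' target). The inferred mapping is reported with a message.
#'
#' @param path path to the file.
#' @param dialect one of `"auto"` (by extension), `"xlsx"`, `"csv"`,
#'   `"tsv"`, `"sif"`.
#' @return a `curated_database` with fields `ages` (character),
#'   `receptors` (data.frame identifier/class), `interactions`
#'   (data.frame of interaction records) and `references` (character).
#' @export
read_database <- function(path, dialect = c("auto", "xlsx", "csv", "tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      xlsx = , xls = "xlsx",
      sif = "sif",
      tsv = , txt = "tsv",
      csv = "csv",
      stop("cannot infer dialect from extension '", ext, "'; pass dialect explicitly")
    )
  }
  switch(dialect,
    xlsx = read_database_xlsx(path),
    csv = read_database_table(path, sep = ","),
    tsv = read_database_table(path, sep = "\t"),
    sif = {
      net <- read_sif(path)
      curated_database(interactions = net$records)
    }
  )
}

curated_database <- function(ages = character(0),
                             receptors = data.frame(identifier = character(0), class = character(0)),
                             interactions,
                             references = character(0)) {
  if (nrow(interactions) < 1) {
    stop("schema error: no interaction rows found")
  }
  structure(
    list(ages = ages, receptors = receptors, interactions = interactions,
         references = references),
    class = "curated_database"
  )
}

#' @export
print.curated_database <- function(x, ...) {
  cat(sprintf(
    "curated_database: %d interactions, %d AGEs, %d receptors, %d references\n",
    nrow(x$interactions), length(x$ages), nrow(x$receptors), length(x$references)
  ))
  invisible(x)
}

read_database_xlsx <- function(path) {
  sheets <- tryCatch(readxl::excel_sheets(path),
    error = function(e) stop("unreadable workbook: ", conditionMessage(e))
  )
  key <- tolower(gsub("[^a-z0-9]+", "", tolower(sheets)))
  grab <- function(pattern) sheets[grepl(pattern, key)][1]

  ages_sheet <- grab("^ages?$")
  receptors_sheet <- grab("^receptors?$")
  # the interaction sheet carries both partner classes in its name (e.g. AGE-TRPV1)
  inter_sheet <- grab("(agetrpv1|^interactions?$|^edges?$|^links?$)")
  refs_sheet <- grab("^references?$")
  known <- c(ages_sheet, receptors_sheet, inter_sheet, refs_sheet, grab("^analysis$"))
  unknown <- setdiff(sheets, known[!is.na(known)])
  if (length(unknown)) {
    warning("ignoring unrecognized sheet(s): ", paste(unknown, collapse = ", "))
  }
  if (is.na(inter_sheet)) {
    stop("schema error: no interaction sheet found; sheets seen: ",
         paste(sheets, collapse = ", "))
  }

  ages <- character(0)
  if (!is.na(ages_sheet)) {
    df <- as.data.frame(readxl::read_excel(path, sheet = ages_sheet, col_types = "text"))
    if (ncol(df) >= 1) ages <- trimws(stats::na.omit(as.character(df[[1]])))
  }
  receptors <- data.frame(identifier = character(0), class = character(0))
  if (!is.na(receptors_sheet)) {
    df <- as.data.frame(readxl::read_excel(path, sheet = receptors_sheet, col_types = "text"))
    if (ncol(df) >= 1) {
      receptors <- data.frame(
        identifier = trimws(as.character(df[[1]])),
        class = if (ncol(df) >= 2) trimws(as.character(df[[2]])) else NA_character_,
        stringsAsFactors = FALSE
      )
      receptors <- receptors[!is.na(receptors$identifier) & nzchar(receptors$identifier), ]
    }
  }
  references <- character(0)
  if (!is.na(refs_sheet)) {
    df <- as.data.frame(readxl::read_excel(path, sheet = refs_sheet, col_types = "text"))
    if (ncol(df) >= 1) references <- trimws(stats::na.omit(as.character(df[[1]])))
  }

  raw <- as.data.frame(readxl::read_excel(path, sheet = inter_sheet, col_types = "text"))
  interactions <- sniff_interaction_columns(raw, header = TRUE,
                                            context = paste0("sheet '", inter_sheet, "'"))
  if (nrow(interactions) < 1) {
    stop("schema error: interaction sheet '", inter_sheet, "' has no rows; sheets seen: ",
         paste(sheets, collapse = ", "))
  }
  curated_database(ages = ages, receptors = receptors,
                   interactions = interactions, references = references)
}

read_database_table <- function(path, sep) {
  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character", quote = "\"", comment.char = ""),
    error = function(e) stop("unreadable file: ", conditionMessage(e))
  )
  if (nrow(raw) < 1) stop("schema error: no interaction rows found in ", path)
  first <- tolower(trimws(as.character(raw[1, ])))
  has_header <- any(first %in% c("source", "target"))
  if (has_header) {
    names(raw) <- trimws(as.character(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(raw) < 1) stop("schema error: no interaction rows found in ", path)
  interactions <- sniff_interaction_columns(raw, header = has_header, context = path)
  curated_database(interactions = interactions)
}

# Decide which columns hold source/target/type/provenance.
sniff_interaction_columns <- function(df, header, context) {
  nm <- tolower(names(df))
  pick <- function(...) {
    hit <- which(nm %in% c(...))
    if (length(hit)) hit[1] else NA_integer_
  }
  src <- pick("source", "from", "node1", "molecule1")
  tgt <- pick("target", "to", "node2", "molecule2")
  if (header && !is.na(src) && !is.na(tgt)) {
    typ <- pick("interaction_type", "interaction", "type")
    prov <- pick("provenance", "pmid", "reference", "ref")
    message(context, ": using named columns (source=", names(df)[src],
            ", target=", names(df)[tgt], ")")
  } else if (ncol(df) >= 3) {
    src <- 1L; typ <- 2L; tgt <- 3L
    prov <- if (ncol(df) >= 4) 4L else NA_integer_
    message(context, ": no named columns; assuming SIF order ",
            "(col1=source, col2=interaction type, col3=target)")
  } else if (ncol(df) == 2) {
    src <- 1L; tgt <- 2L; typ <- NA_integer_; prov <- NA_integer_
    message(context, ": two columns; assuming (source, target)")
  } else {
    stop("schema error: cannot locate source/target columns in ", context)
  }
  out <- data.frame(
    source = trimws(as.character(df[[src]])),
    target = trimws(as.character(df[[tgt]])),
    interaction_type = if (!is.na(typ)) trimws(as.character(df[[typ]])) else NA_character_,
    provenance = if (!is.na(prov)) trimws(as.character(df[[prov]])) else NA_character_,
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$source) & !is.na(out$target) &
             nzchar(out$source) & nzchar(out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a network from a SIF file
#'
#' Lines are `source<TAB>interaction type<TAB>target`; a line with a single
#' field declares an isolated node. Space-delimited SIF is accepted when a
#' line contains no tab.
#'
#' @param path path to the SIF file.
#' @return a `molecular_network`.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  src <- character(0); typ <- character(0); tgt <- character(0); iso <- character(0)
  for (i in which(keep)) {
    fields <- strsplit(lines[i], if (grepl("\t", lines[i])) "\t" else "[ ]+")[[1]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    if (length(fields) == 1) {
      iso <- c(iso, fields)
    } else if (length(fields) >= 3) {
      # SIF allows several targets on one line, all sharing the interaction type
      for (t in fields[-(1:2)]) {
        src <- c(src, fields[1]); typ <- c(typ, fields[2]); tgt <- c(tgt, t)
      }
    } else {
      stop("malformed SIF line ", i, " (2 fields): ", lines[i])
    }
  }
  records <- data.frame(source = src, target = tgt, interaction_type = typ,
                        provenance = NA_character_, stringsAsFactors = FALSE)
  molecular_network(records, nodes = iso)
}

#' Write a network to a SIF file
#'
#' Every interaction record is written verbatim, one per line; isolated
#' nodes are written as single-field lines.
#'
#' @param net a `molecular_network`.
#' @param path output path.
#' @export
write_sif <- function(net, path) {
  typ <- net$records$interaction_type
  typ[is.na(typ) | !nzchar(typ)] <- "interacts"
  lines <- sprintf("%s\t%s\t%s", net$records$source, typ, net$records$target)
  endpoints <- unique(c(net$records$source, net$records$target))
  iso <- setdiff(net$nodes, endpoints)
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Write a network to GraphML
#'
#' Exports the simple graph (self-loops and duplicate records collapsed)
#' with node names and compartment labels as attributes, for interchange
#' with Cytoscape-style tools.
#'
#' @param net a `molecular_network`.
#' @param path output path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph_simple(net), path, format = "graphml")
  invisible(path)
}

#' Write a node-metric table to CSV
#'
#' @param metrics a data.frame, one row per node (see [node_metrics()]).
#' @param path output path.
#' @export
write_node_table <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
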