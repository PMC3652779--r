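## I/O for every external table the pipeline touches. All readers validate on
## the way in and all writers round-trip to at least 6 significant digits.

VALID_WELLS <- as.vector(outer(LETTERS[1:8], 1:12, paste0))

new_raw_screen_set <- function(wells, panel) {
  structure(list(wells = wells, panel = panel), class = "raw_screen_set")
}

#' @export
print.raw_screen_set <- function(x, ...) {
  cat("raw_screen_set:", nrow(x$wells), "wells,",
      length(unique(x$wells$plate_id)), "plates,",
      length(x$panel), "elements\n")
  invisible(x)
}

#' Read a per-well plate screen table
#'
#' The canonical ingest format is a CSV with columns `plate_id`, `run_id`
#' (the instrument day), `well` (A1-H12), `strain_id`, `role`
#' (`control`/`mutant`), `replicate`, `od600` and one column per panel
#' element holding the measured concentration in ppm. Header matching is
#' case-insensitive and column order is free.
#'
#' @param path Path to the CSV file.
#' @param panel An [element_panel()]; every panel element must be present as
#'   a column.
#' @return A `raw_screen_set`: a list with `wells` (validated data frame with
#'   canonical column names) and `panel`.
#' @export
read_plate_table <- function(path, panel) {
  stopifnot(inherits(panel, "element_panel"))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("plate_id", "run_id", "well", "strain_id", "role",
                 "replicate", "od600")
  lower <- tolower(names(df))
  idx <- match(tolower(meta_cols), lower)
  if (anyNA(idx)) {
    stop("plate table is missing column(s): ",
         paste(meta_cols[is.na(idx)], collapse = ", "))
  }
  eidx <- match(tolower(panel), lower)
  if (anyNA(eidx)) {
    stop("plate table is missing element column(s): ",
         paste(panel[is.na(eidx)], collapse = ", "))
  }
  wells <- df[, c(idx, eidx)]
  names(wells) <- c(meta_cols, as.character(panel))

  for (col in c(meta_cols[1:5])) wells[[col]] <- as.character(wells[[col]])
  if (any(is.na(wells$plate_id) | is.na(wells$well) | is.na(wells$strain_id))) {
    stop("plate table has rows with missing plate_id/well/strain_id")
  }
  bad_well <- !wells$well %in% VALID_WELLS
  if (any(bad_well)) {
    stop("well id(s) outside the 96-well A1-H12 grid: ",
         paste(unique(wells$well[bad_well]), collapse = ", "))
  }
  if (!all(wells$role %in% c("control", "mutant"))) {
    stop("role must be 'control' or 'mutant'")
  }
  wells$replicate <- as.integer(wells$replicate)
  if (any(is.na(wells$replicate) | wells$replicate < 1L)) {
    stop("replicate must be a positive integer")
  }
  wells$od600 <- suppressWarnings(as.numeric(wells$od600))
  if (anyNA(wells$od600)) stop("non-numeric od600 value(s)")
  if (any(wells$od600 <= 0)) {
    stop("od600 must be > 0; offending well(s): ",
         paste(utils::head(wells$well[wells$od600 <= 0], 5), collapse = ", "))
  }
  for (el in as.character(panel)) {
    v <- suppressWarnings(as.numeric(wells[[el]]))
    if (anyNA(v) && !all(is.na(wells[[el]]) == is.na(v))) {
      stop("non-numeric concentration for element ", el, " at row(s) ",
           paste(utils::head(which(is.na(v) != is.na(wells[[el]])), 5),
                 collapse = ", "))
    }
    if (anyNA(v)) stop("missing concentration for element ", el)
    if (any(v < 0)) stop("negative concentration for element ", el)
    wells[[el]] <- v
  }
  new_raw_screen_set(wells, panel)
}

#' Write a raw screen set back to the plate CSV schema
#' @param raw A `raw_screen_set`.
#' @param path Output CSV path.
#' @export
write_plate_table <- function(raw, path) {
  stopifnot(inherits(raw, "raw_screen_set"))
  utils::write.csv(raw$wells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene x element moderated-Z table
#'
#' Reads supplementary-style tables with one row per gene and one column per
#' element. Cells that are blank or `"-"` denote an absent (non-significant,
#' unreported) value, following the dash convention of published tables.
#'
#' @param path CSV path with columns `gene_id`, optional `gene_name`, and a
#'   subset of panel element columns (case-insensitive).
#' @param panel An [element_panel()].
#' @return A `z_matrix`: numeric matrix (genes x panel elements, `NA` where
#'   absent) with a `gene_name` attribute.
#' @export
read_ztable <- function(path, panel) {
  stopifnot(inherits(panel, "element_panel"))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  lower <- tolower(names(df))
  gid <- match("gene_id", lower)
  if (is.na(gid)) stop("Z table is missing column gene_id")
  gene_id <- df[[gid]]
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup) > 0) {
    stop("duplicate gene_id in Z table: ", paste(dup, collapse = ", "))
  }
  gname_i <- match("gene_name", lower)
  gene_name <- if (!is.na(gname_i)) df[[gname_i]] else rep(NA_character_, nrow(df))

  Z <- matrix(NA_real_, nrow(df), length(panel),
              dimnames = list(gene_id, as.character(panel)))
  eidx <- match(tolower(panel), lower)
  for (j in seq_along(panel)) {
    if (is.na(eidx[j])) next
    cell <- trimws(df[[eidx[j]]])
    cell[cell %in% c("", "-")] <- NA_character_
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(v))
    if (length(bad) > 0) {
      stop("non-numeric Z for element ", panel[j], " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    Z[, j] <- v
  }
  attr(Z, "gene_name") <- stats::setNames(gene_name, gene_id)
  class(Z) <- c("z_matrix", class(Z))
  Z
}

#' Read interactions from a BioGRID TAB 2.0/3.0 file
#'
#' Accepts the tab-delimited BioGRID layouts whose first 17 columns are
#' shared between TAB 2.0 (24 columns) and TAB 3.0 (>= 35 columns):
#' systematic names in columns 6-7, official symbols in 8-9, experimental
#' system type (`physical`/`genetic`) in column 13 and organism ids in 16-17.
#' Systematic ORF names are preferred as identifiers; rows lacking them fall
#' back to the official symbol with a warning. Self-interactions are dropped
#' and duplicates collapsed to one record per unordered pair and type.
#'
#' @param path Path to the TAB file (comment lines starting `#` are skipped).
#' @param organism_filter Optional organism id; when given, both interactors
#'   must match.
#' @return Data frame with columns `gene_a`, `gene_b` (canonically ordered,
#'   `gene_a < gene_b`) and `itype`.
#' @export
read_biogrid_tab <- function(path, organism_filter = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      itype = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(fields[[1]])
  if (ncol < 17) {
    stop("unrecognized BioGRID column layout: detected ", ncol,
         " columns (TAB 2.0 has 24, TAB 3.0 has >= 35)")
  }
  get <- function(i) vapply(fields, function(f) f[i], character(1))
  sys_a <- get(6); sys_b <- get(7)
  sym_a <- get(8); sym_b <- get(9)
  itype <- tolower(get(13))
  org_a <- get(16); org_b <- get(17)

  keep <- itype %in% c("physical", "genetic")
  if (!is.null(organism_filter)) {
    keep <- keep & org_a == as.character(organism_filter) &
      org_b == as.character(organism_filter)
  }
  missing_sys <- sys_a %in% c("-", "") | sys_b %in% c("-", "")
  if (any(missing_sys & keep)) {
    warning(sum(missing_sys & keep),
            " interaction(s) lack systematic names; using official symbols")
  }
  a <- ifelse(sys_a %in% c("-", ""), sym_a, sys_a)
  b <- ifelse(sys_b %in% c("-", ""), sym_b, sys_b)
  keep <- keep & a != b   # self-loops out
  a <- a[keep]; b <- b[keep]; itype <- itype[keep]

  ga <- pmin(a, b); gb <- pmax(a, b)
  key <- paste(ga, gb, itype, sep = "\r")
  first <- !duplicated(key)
  data.frame(gene_a = ga[first], gene_b = gb[first], itype = itype[first],
             stringsAsFactors = FALSE)
}

#' Write significance calls and clusters to CSV
#'
#' Writes `<prefix>_calls.csv` (one row per significant gene x element with
#' Z, q, perCh, annealing flag and effect group) and, when a cluster set is
#' supplied, `<prefix>_clusters.csv` (gene membership with pattern key) plus
#' `<prefix>_cluster_profiles.csv` (per-cluster median Z profiles). Values
#' re-read from these files agree with the originals to at least 6
#' significant digits.
#'
#' @param callset A `call_set` from [call_significance()].
#' @param clusterset Optional `cluster_set` from [esc_cluster()].
#' @param path_prefix Path prefix for the output files.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(callset, clusterset = NULL, path_prefix) {
  stopifnot(inherits(callset, "call_set"))
  sig <- which(callset$sign != 0, arr.ind = TRUE)
  genes <- rownames(callset$sign)[sig[, 1]]
  elems <- colnames(callset$sign)[sig[, 2]]
  calls <- data.frame(
    gene_id = genes,
    element = elems,
    Z = callset$Z[sig],
    q = callset$q[sig],
    sign = callset$sign[sig],
    perCh = callset$perCh[sig],
    annealing_pass = callset$annealing_pass[sig],
    group = unname(callset$group[genes]),
    stringsAsFactors = FALSE
  )
  calls <- calls[order(calls$gene_id, calls$element), , drop = FALSE]
  paths <- paste0(path_prefix, "_calls.csv")
  utils::write.csv(calls, paths[1], row.names = FALSE, quote = FALSE)

  if (!is.null(clusterset)) {
    stopifnot(inherits(clusterset, "cluster_set"))
    memb <- cluster_membership(clusterset)
    p2 <- paste0(path_prefix, "_clusters.csv")
    utils::write.csv(memb, p2, row.names = FALSE, quote = FALSE)
    prof <- cluster_profile_table(clusterset)
    p3 <- paste0(path_prefix, "_cluster_profiles.csv")
    utils::write.csv(prof, p3, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p2, p3)
  }
  invisible(paths)
}

#' Read a significance-calls CSV written by [write_results()]
#' @param path Path to a `*_calls.csv` file.
#' @return Data frame of significant calls.
#' @export
read_results_calls <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## ---- ontology parsing primitives (used by the enrichment module) ----

#' Read an OBO 1.2 ontology file
#'
#' Minimal reader for `[Term]` stanzas: keeps id, name, namespace, `is_a`
#' parents and `relationship: part_of` parents; obsolete terms are skipped.
#'
#' @param path Path to an OBO 1.2 file.
#' @return List with `terms` (data frame id/name/namespace) and `parents`
#'   (named list mapping a term id to its parent ids).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(); names_ <- character(); ns <- character()
  parents <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && nzchar(cur$id)) {
      ids <<- c(ids, cur$id)
      names_ <<- c(names_, cur$name)
      ns <<- c(ns, cur$namespace)
      parents[[cur$id]] <<- unique(cur$parents)
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(sub("!.*$", "", ln))
    if (ln == "[Term]") {
      flush()
      cur <- list(id = "", name = NA_character_, namespace = NA_character_,
                  parents = character(), obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(); cur <- NULL; in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (startsWith(ln, "id:")) cur$id <- trimws(substring(ln, 4))
      else if (startsWith(ln, "name:")) cur$name <- trimws(substring(ln, 6))
      else if (startsWith(ln, "namespace:")) cur$namespace <- trimws(substring(ln, 11))
      else if (startsWith(ln, "is_a:")) {
        target <- strsplit(trimws(substring(ln, 6)), "\\s+")[[1]][1]
        cur$parents <- c(cur$parents, target)
      } else if (startsWith(ln, "relationship:")) {
        parts <- strsplit(trimws(substring(ln, 14)), "\\s+")[[1]]
        if (length(parts) >= 2 && parts[1] == "part_of") {
          cur$parents <- c(cur$parents, parts[2])
        }
      } else if (startsWith(ln, "is_obsolete:")) {
        cur$obsolete <- grepl("true", ln)
      }
    }
  }
  flush()
  list(terms = data.frame(id = ids, name = names_, namespace = ns,
                          stringsAsFactors = FALSE),
       parents = parents)
}

#' Read gene annotations from a GAF 2.x file
#'
#' @param path Path to a GAF file; `!` comment lines are skipped.
#' @param id_column Which column carries the gene identifier: 3 (DB object
#'   symbol, default) or 2 (DB object id).
#' @return Data frame with columns `gene` and `term`; `NOT`-qualified rows
#'   are excluded.
#' @export
read_gaf <- function(path, id_column = 3) {
  stopifnot(id_column %in% c(2, 3))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) {
    return(data.frame(gene = character(), term = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 5
  if (any(short)) stop("GAF line(s) with fewer than 5 columns")
  gene <- vapply(fields, function(f) f[id_column], character(1))
  qual <- vapply(fields, function(f) f[4], character(1))
  term <- vapply(fields, function(f) f[5], character(1))
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  unique(data.frame(gene = gene[keep], term = term[keep],
                    stringsAsFactors = FALSE))
}
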