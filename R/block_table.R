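#' Synteny block tables
#'
#' A block table stores one row per homologous synteny block, with an integer
#' `block_id`, an ancestral `colour` label (1-21, the core-eudicot ancestral
#' chromosomes), an optional logical `polarity_determinate` flag, and for each
#' placed genome five columns named `<genome>_scaffold`, `<genome>_start`,
#' `<genome>_end`, `<genome>_strand` and `<genome>_genes`.  Coordinates are
#' 1-based inclusive gene indices (ordinal gene positions on the scaffold, not
#' base pairs); `genes` is the number of orthologous genes the block retains
#' in that genome, which can be smaller than the span because of
#' fractionation.
#'
#' @param records a data.frame with the columns described above.
#' @param colour_count number of valid colour labels (default 21).
#' @return the validated data.frame with class `block_table` and attribute
#'   `genome_names`.
#' @export
block_table <- function(records, colour_count = 21L) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("block_id", "colour")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("block table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"polarity_determinate" %in% names(records))
    records$polarity_determinate <- TRUE
  genomes <- table_genome_names(records)
  if (length(genomes) < 1L && nrow(records) > 0L)
    stop("block table places no genome (no '<genome>_scaffold' columns)")
  if (nrow(records)) {
    if (anyDuplicated(records$block_id))
      stop("duplicate block_id in table: ",
           paste(unique(records$block_id[duplicated(records$block_id)]),
                 collapse = ", "))
    bad_col <- !is.na(records$colour) &
      (records$colour < 1 | records$colour > colour_count)
    if (any(bad_col))
      stop("colour out of range 1..", colour_count, " for block_id ",
           paste(records$block_id[bad_col], collapse = ", "))
    for (g in genomes) {
      s <- records[[paste0(g, "_start")]]
      e <- records[[paste0(g, "_end")]]
      n <- records[[paste0(g, "_genes")]]
      st <- records[[paste0(g, "_strand")]]
      if (any(s > e, na.rm = TRUE))
        stop("start > end in genome '", g, "' for block_id ",
             paste(records$block_id[which(s > e)], collapse = ", "))
      if (any(n > e - s + 1, na.rm = TRUE))
        stop("gene count exceeds span in genome '", g, "' for block_id ",
             paste(records$block_id[which(n > e - s + 1)], collapse = ", "))
      if (any(n < 0, na.rm = TRUE))
        stop("negative gene count in genome '", g, "'")
      ok_strand <- is.na(st) | st %in% c("+", "-")
      if (!all(ok_strand))
        stop("unknown strand symbol in genome '", g, "': ",
             paste(unique(st[!ok_strand]), collapse = ", "))
    }
  }
  structure(records, class = c("block_table", "data.frame"),
            genome_names = genomes)
}

table_genome_names <- function(records) {
  cn <- names(records)
  pref <- sub("_scaffold$", "", cn[grepl("_scaffold$", cn)])
  keep <- vapply(pref, function(g)
    all(paste0(g, c("_start", "_end", "_strand", "_genes")) %in% cn),
    logical(1))
  unname(pref[keep])
}

#' Genome names placed in a block table
#' @param t a [block_table].
#' @return character vector of genome names.
#' @export
genomes_of_table <- function(t) {
  gn <- attr(t, "genome_names")
  if (is.null(gn)) gn <- table_genome_names(t)
  gn
}

#' Read a block table from TSV
#'
#' Tab-separated UTF-8 with a header row; `.` denotes a missing optional
#' field.  See [block_table()] for the column contract.
#'
#' @param path path to a TSV file.
#' @param colour_count number of valid colour labels (default 21).
#' @return a [block_table]; row order is preserved.
#' @export
read_block_table <- function(path, colour_count = 21L) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = ".",
                          quote = "", comment.char = "")
  if (!nrow(df)) {
    # empty body is a valid (empty) table
    df$polarity_determinate <- logical(0)
  }
  if ("polarity_determinate" %in% names(df))
    df$polarity_determinate <- as.logical(df$polarity_determinate)
  block_table(df, colour_count = colour_count)
}

#' Write a block table as TSV
#' @param t a [block_table].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(t, path) {
  df <- as.data.frame(t)
  for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a signed block-order genome from a block table
#'
#' Blocks on each scaffold are ordered by start gene index; the block sign is
#' its strand in that genome; scaffolds become chromosomes, ordered
#' lexicographically by scaffold id (order is irrelevant to every distance
#' used downstream but keeps output deterministic).
#'
#' @param t a [block_table].
#' @param genome_name one of `genomes_of_table(t)`.
#' @return a [block_genome].
#' @export
genome_from_table <- function(t, genome_name) {
  if (!genome_name %in% genomes_of_table(t))
    stop("genome '", genome_name, "' is not placed in this table")
  scf <- t[[paste0(genome_name, "_scaffold")]]
  s <- t[[paste0(genome_name, "_start")]]
  e <- t[[paste0(genome_name, "_end")]]
  st <- t[[paste0(genome_name, "_strand")]]
  keep <- !is.na(scf)
  scf <- as.character(scf[keep]); s <- s[keep]; e <- e[keep]; st <- st[keep]
  ids <- t$block_id[keep]
  chromosomes <- list()
  for (sc in sort(unique(scf))) {
    i <- which(scf == sc)
    i <- i[order(s[i])]
    if (length(i) > 1L) {
      ov <- which(s[i][-1] <= e[i][-length(i)])
      if (length(ov))
        stop("overlapping block spans on scaffold '", sc, "' of genome '",
             genome_name, "': block_id ", ids[i][ov[1]], " and ",
             ids[i][ov[1] + 1L])
    }
    chromosomes[[length(chromosomes) + 1L]] <-
      as.integer(ids[i] * ifelse(st[i] == "-", -1L, 1L))
  }
  block_genome(chromosomes, name = genome_name)
}
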