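#' Signed block genome
#'
#' A genome represented as an unordered set of linear chromosomes, each an
#' ordered sequence of signed synteny-block identifiers.  The sign carries the
#' strand (polarity) of the block.  A chromosome and its reverse complement
#' (reversed order, all signs flipped) denote the same molecule.
#'
#' @param chromosomes list of integer vectors, one per chromosome; entries are
#'   non-zero signed block identifiers.
#' @param name single character label for the genome.
#' @return an object of class `block_genome` with fields `name` and
#'   `chromosomes`.
#' @examples
#' g <- block_genome(list(c(1L, -2L, 3L), 4L), name = "toy")
#' n_blocks(g)
#' @export
block_genome <- function(chromosomes, name = "genome") {
  if (!is.list(chromosomes)) chromosomes <- list(chromosomes)
  chromosomes <- unname(lapply(chromosomes, function(x) as.integer(unname(x))))
  g <- structure(list(name = as.character(name)[1], chromosomes = chromosomes),
                 class = "block_genome")
  validate_block_genome(g)
  g
}

validate_block_genome <- function(g) {
  if (length(g$chromosomes) < 1L)
    stop("genome '", g$name, "' must have at least one chromosome")
  for (chr in g$chromosomes) {
    if (length(chr) == 0L) stop("genome '", g$name, "' has an empty chromosome")
    if (anyNA(chr) || any(chr == 0L))
      stop("genome '", g$name, "' has missing or zero block identifiers")
  }
  ids <- abs(unlist(g$chromosomes))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate block id in genome '", g$name, "': ",
         paste(sort(unique(dup)), collapse = ", "))
  invisible(g)
}

#' @export
print.block_genome <- function(x, ...) {
  cat("<block_genome> ", x$name, ": ", length(x$chromosomes),
      " chromosome(s), ", n_blocks(x), " block(s)\n", sep = "")
  for (i in seq_along(x$chromosomes))
    cat("  [", i, "] ", paste(x$chromosomes[[i]], collapse = " "), "\n",
        sep = "")
  invisible(x)
}

#' Number of blocks in a genome
#' @param g a [block_genome].
#' @return integer count of distinct blocks.
#' @export
n_blocks <- function(g) length(unlist(g$chromosomes))

#' Unsigned block identifiers of a genome
#' @param g a [block_genome].
#' @return sorted integer vector of block ids.
#' @export
block_ids <- function(g)
  sort(abs(as.integer(unlist(g$chromosomes, use.names = FALSE))))

#' Read a genome from GRIMM-style text
#'
#' The format is the de facto standard of block-order rearrangement tools
#' (GRIMM/UniMoG): one `>name` header, then chromosomes as whitespace-separated
#' signed integers, each chromosome terminated by `$`.  Only linear
#' chromosomes are accepted.
#'
#' @param path path to a text file.
#' @return a [block_genome].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1], ">"))
    stop("GRIMM format error: expected '>name' header in ", path)
  name <- trimws(sub("^>", "", lines[1]))
  body <- paste(lines[-1], collapse = " ")
  if (grepl("@", body, fixed = TRUE))
    stop("circular chromosomes ('@' terminator) are not supported")
  toks <- strsplit(trimws(body), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  chromosomes <- list()
  cur <- integer(0)
  for (tk in toks) {
    if (tk == "$") {
      if (length(cur) == 0L)
        stop("GRIMM format error: empty chromosome in ", path)
      chromosomes[[length(chromosomes) + 1L]] <- cur
      cur <- integer(0)
    } else {
      v <- suppressWarnings(as.integer(tk))
      if (is.na(v) || v == 0L)
        stop("GRIMM format error: bad token '", tk, "' in ", path)
      cur <- c(cur, v)
    }
  }
  if (length(cur))
    stop("GRIMM format error: final chromosome not terminated by '$' in ", path)
  block_genome(chromosomes, name = name)
}

#' Write a genome as GRIMM-style text
#'
#' Inverse of [read_genome()]: `read_genome(write_genome(g, p))` reproduces
#' `g` exactly.
#'
#' @param g a [block_genome].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path) {
  validate_block_genome(g)
  lines <- c(paste0(">", g$name),
             vapply(g$chromosomes,
                    function(chr) paste(c(chr, "$"), collapse = " "),
                    character(1)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write genome to ", path)
  invisible(path)
}

#' Canonical form of a genome
#'
#' Orients every chromosome so that its end block of smallest magnitude comes
#' first with positive sign preferred, and sorts chromosomes by the magnitude
#' of their first block.  Two genomes describing the same chromosome set have
#' identical canonical forms, which makes "number of distinct medians"
#' well-defined.
#'
#' @param g a [block_genome].
#' @return a [block_genome] in canonical form.
#' @export
canonical_genome <- function(g) {
  canon_chr <- function(chr) {
    rev_chr <- -rev(chr)
    a <- abs(chr[1]); b <- abs(rev_chr[1])
    if (a < b) return(chr)
    if (b < a) return(rev_chr)
    # same end magnitudes (single block, or palindromic ends): prefer + sign
    if (chr[1] > 0) chr else rev_chr
  }
  chrs <- lapply(g$chromosomes, canon_chr)
  ord <- order(vapply(chrs, function(chr) abs(chr[1]), numeric(1)))
  block_genome(chrs[ord], name = g$name)
}

#' Test whether two genomes are identical up to chromosome order and flips
#' @param a,b [block_genome] objects.
#' @return logical.
#' @export
same_genome <- function(a, b) {
  identical(canonical_genome(a)$chromosomes, canonical_genome(b)$chromosomes)
}

# deterministic key for dedup of genomes
genome_key <- function(g) {
  paste(vapply(canonical_genome(g)$chromosomes, paste, character(1),
               collapse = " "), collapse = " $ ")
}
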