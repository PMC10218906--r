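# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# utf8 codes for A C G T
BASE_INT <- c(A = 65L, C = 67L, G = 71L, T = 84L)

# complement of a character vector of bases (keeps N and others as-is via chartr)
comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# reverse-complement of a character vector of DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

other_strand <- function(s) ifelse(s == "+", "-", "+")

# reference-consumed width of CIGAR strings (M, =, X, D, N consume reference)
cigar_ref_width <- function(cigar) {
  simple <- grepl("^[0-9]+M$", cigar)
  out <- integer(length(cigar))
  out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  if (any(!simple)) {
    out[!simple] <- vapply(cigar[!simple], function(cg) {
      ops <- cigar_ops(cg)
      sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
    }, integer(1), USE.NAMES = FALSE)
  }
  out
}

cigar_ops <- function(cg) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
  tok <- regmatches(cg, list(m))[[1]]
  list(
    len = as.integer(sub("[A-Z=]$", "", tok)),
    op = sub("^[0-9]+", "", tok)
  )
}

# seeded evaluation that does not disturb the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

as_contig_set <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    return(reference)
  }
  if (inherits(reference, "tribe_genome")) {
    return(reference$contigs)
  }
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    return(Biostrings::readDNAStringSet(reference))
  }
  if (is.character(reference)) {
    return(Biostrings::DNAStringSet(reference))
  }
  abort("reference must be a DNAStringSet, a tribe_genome, or a FASTA path")
}
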