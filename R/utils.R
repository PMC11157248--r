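# Internal helpers: error classes, RNG scoping, DNA utilities, small I/O.

stop_input <- function(msg, call. = FALSE) {
  stop(structure(class = c("cascadeHOR_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_param <- function(msg) {
  stop(structure(class = c("cascadeHOR_param_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n, at = 0.5) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTNacgtn]*$" else "^[ACGTacgt]*$"
  if (!grepl(pat, x)) {
    stop_input(sprintf("%s contains characters outside {A,C,G,T%s}",
                       what, if (allow_n) ",N" else ""))
  }
  toupper(x)
}

# Coerce a subject/query argument (path, character vector, DNAString(Set))
# into a named character vector of uppercase sequences.
as_dna_chr <- function(x, what = "sequence") {
  if (inherits(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(toupper(out))
  }
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !grepl("^[ACGTNacgtn]*$", x)) {
    if (file.size(x) == 0) return(character(0))  # empty FASTA: no sequences
    ss <- Biostrings::readDNAStringSet(x)
    out <- toupper(as.character(ss))
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(vapply(x, check_dna, character(1), what = what))
  }
  stop_input(sprintf("cannot interpret %s as DNA (path, character or DNAStringSet expected)", what))
}

write_tsv <- function(df, path) {
  # list columns are serialized as comma-joined strings
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, function(v) paste(v, collapse = ","), character(1)) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

fmt_family <- function(label) paste0("t", label)
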