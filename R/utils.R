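# Internal helpers: deterministic seeding and small IO conveniences.

# Derive a stream-specific seed from a single global seed so that the
# different generators (annotations, genomes, ASV tables, orthogroups) are
# reproducible independently of the order in which they are called.
# 48271 is the MINSTD multiplier; the modulus keeps results in 32-bit range.
forkSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629 + 1)
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

readTsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    ...)
}

#' Write a matrix as a TSV file with a leading id column
#'
#' @param m a matrix with row and column names.
#' @param path output file path.
#' @param idColumn name for the leading row-id column.
#' @return `path`, invisibly.
#' @export
writeMatrixTsv <- function(m, path, idColumn = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# condition constructors: config errors (exit-style class "beeprofiler_config_error")
configError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("beeprofiler_config_error", "error")))
}

stageError <- function(stage, parent) {
  stop(errorCondition(
    sprintf("stage '%s' failed: %s", stage, conditionMessage(parent)),
    class = c("beeprofiler_stage_error", "error")))
}
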