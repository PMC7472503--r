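# REBA lookup tables A, B and C.
#
# The tables ship as plain CSV under inst/extdata so they remain auditable
# and versioned as data, not code; they are parsed once per session into
# dense integer arrays and verified against recorded MD5 checksums, since
# transcription typos are the dominant failure mode for worksheet tables.

.reba_tables <- new.env(parent = emptyenv())

TABLE_MD5 <- c(
  reba_table_a.csv = "c7f757f4a48f9b591d5a8bbdefbb8474",
  reba_table_b.csv = "3ef3e7694b85172374f4369f0d7f153e",
  reba_table_c.csv = "9c26f294fc7f92d033aac90e253b0a84"
)

table_file <- function(name) {
  path <- system.file("extdata", name, package = "quickreba")
  if (!nzchar(path)) stop("table file not found: ", name, call. = FALSE)
  sum <- unname(tools::md5sum(path))
  if (!is.na(TABLE_MD5[name]) && sum != TABLE_MD5[name]) {
    stop("checksum mismatch for ", name,
         ": the shipped REBA table was modified", call. = FALSE)
  }
  path
}

load_reba_tables <- function() {
  if (!is.null(.reba_tables$A)) return(invisible())
  a <- utils::read.csv(table_file("reba_table_a.csv"))
  A <- array(NA_integer_, dim = c(3, 5, 4))
  for (i in seq_len(nrow(a))) {
    A[a$neck[i], a$trunk[i], ] <- as.integer(a[i, 3:6])
  }
  b <- utils::read.csv(table_file("reba_table_b.csv"))
  B <- array(NA_integer_, dim = c(6, 2, 3))
  for (i in seq_len(nrow(b))) {
    B[b$upper_arm[i], b$lower_arm[i], ] <- as.integer(b[i, 3:5])
  }
  cc <- utils::read.csv(table_file("reba_table_c.csv"))
  C <- as.matrix(cc[, -1])
  dimnames(C) <- NULL
  storage.mode(C) <- "integer"
  stopifnot(!anyNA(A), !anyNA(B), !anyNA(C), all(dim(C) == c(12, 12)))
  .reba_tables$A <- A
  .reba_tables$B <- B
  .reba_tables$C <- C
  invisible()
}

#' REBA Table A lookup
#'
#' Posture score for the neck/trunk/legs segment group.
#'
#' @param neck Neck score, 1-3.
#' @param trunk Trunk score, 1-5.
#' @param legs Legs score, 1-4.
#' @return Integer score in 1-9.
#' @export
#' @examples
#' table_a(1, 1, 1)  # 1
#' table_a(3, 5, 4)  # 9
table_a <- function(neck, trunk, legs) {
  load_reba_tables()
  check_index(neck, 3, "neck")
  check_index(trunk, 5, "trunk")
  check_index(legs, 4, "legs")
  .reba_tables$A[neck, trunk, legs]
}

#' REBA Table B lookup
#'
#' Posture score for the upper-arm/lower-arm/wrist segment group.
#'
#' @param upper_arm Upper-arm score, 1-6.
#' @param lower_arm Lower-arm score, 1-2.
#' @param wrist Wrist score, 1-3.
#' @return Integer score in 1-9.
#' @export
#' @examples
#' table_b(1, 1, 1)  # 1
#' table_b(6, 2, 3)  # 9
table_b <- function(upper_arm, lower_arm, wrist) {
  load_reba_tables()
  check_index(upper_arm, 6, "upper_arm")
  check_index(lower_arm, 2, "lower_arm")
  check_index(wrist, 3, "wrist")
  .reba_tables$B[upper_arm, lower_arm, wrist]
}

#' REBA Table C lookup
#'
#' Combines score A and score B. Inputs above 12 clamp to 12, matching the
#' worksheet bounds.
#'
#' @param score_a,score_b Integer scores, 1-12 (higher values clamp).
#' @return Integer score in 1-12.
#' @export
#' @examples
#' table_c(1, 1)    # 1
#' table_c(12, 12)  # 12
table_c <- function(score_a, score_b) {
  load_reba_tables()
  score_a <- min(score_a, 12L)
  score_b <- min(score_b, 12L)
  check_index(score_a, 12, "score_a")
  check_index(score_b, 12, "score_b")
  .reba_tables$C[score_a, score_b]
}

check_index <- function(x, upper, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < 1 || x > upper) {
    stop(what, " score out of range 1..", upper, ": ", x, call. = FALSE)
  }
  invisible()
}
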