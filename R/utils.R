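#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when printing percentages in
#' reports. Base [round()] rounds half to even, which changes the last digit
#' of ratios such as 14.65; half-up rounding makes printed percentages
#' reproducible from exact counts.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` places, halves rounded up.
#' @examples
#' round_half_up(47.28261, 1) # 47.3
#' round_half_up(14.6054, 0)  # 15
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # small epsilon guards against ratios stored a hair below an exact .5
  floor(x * m + 0.5 + 1e-9) / m
}

# Detect the field separator of a delimited text file from its header line.
detect_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L || !nzchar(line)) {
    stop("empty input file: ", path, call. = FALSE)
  }
  n_tab <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
  n_com <- lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else ","
}

# Read a delimited table with header; sep = NULL auto-detects comma vs tab.
read_delim_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

write_delim_table <- function(x, path, sep = ",") {
  # character columns are quoted: some fields (interval labels) contain commas
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
}

# Parse a boolean column that may arrive as logical, 0/1 or "true"/"false".
parse_flag <- function(x, what = "flag") {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1), na.rm = TRUE)) {
      stop("numeric ", what, " column must contain only 0/1", call. = FALSE)
    }
    return(ifelse(is.na(x), FALSE, x == 1))
  }
  v <- tolower(trimws(as.character(x)))
  ok <- v %in% c("0", "1", "true", "false", "t", "f", "")
  if (!all(ok)) {
    stop("cannot parse ", what, " values: ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  }
  v %in% c("1", "true", "t")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
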