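# STAR (RELION dialect) reader/writer.
#
# A STAR document is a named list of blocks. Each block is either a
# key-value list (list(type = "pairs", values = named list)) or a loop
# table (list(type = "loop", data = data.frame)). Block names are the
# part after "data_"; an unnamed block is stored as "".
# Comments (#) are ignored on read; column and block order are preserved
# on write; numeric-looking cells are typed as numbers.

star_type_cell <- function(x) {
  suppressWarnings(num <- as.numeric(x))
  if (!anyNA(num)) {
    ints <- grepl("^-?[0-9]+$", x)
    if (all(ints)) return(as.integer(x))
    return(num)
  }
  x
}

#' Read a STAR file (RELION dialect)
#'
#' Parses `data_` blocks containing either `_key value` pairs or `loop_`
#' tables with `_label` column headers. Numeric columns are typed as
#' numbers; unknown columns are preserved verbatim.
#'
#' @param path path to a STAR text file
#' @return a `star_document`: named list of blocks; each block has
#'   `$type` (`"pairs"` or `"loop"`) and `$values` (named list) or
#'   `$data` (data.frame)
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("STAR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # strip comments and trailing whitespace
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  doc <- list()
  i <- 1L
  nblk <- 0L
  cur_name <- NULL
  cur_pairs <- list()
  store_block <- function(name, blk) {
    if (name %in% names(doc)) name <- tail(make.unique(c(names(doc), name)), 1)
    doc[[name]] <<- blk
  }
  flush_pairs <- function() {
    if (!is.null(cur_name) && length(cur_pairs)) {
      store_block(cur_name, list(type = "pairs", values = cur_pairs))
    }
    cur_pairs <<- list()
  }
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "") { i <- i + 1L; next }
    if (startsWith(ln, "data_")) {
      flush_pairs()
      nblk <- nblk + 1L
      cur_name <- substring(ln, 6L)
      if (cur_name == "") cur_name <- paste0("block_", nblk)
      i <- i + 1L
    } else if (ln == "loop_") {
      if (is.null(cur_name)) stop("loop_ before any data_ block at line ", i)
      i <- i + 1L
      labels <- character()
      while (i <= length(lines) && startsWith(lines[i], "_")) {
        lab <- strsplit(lines[i], "[[:space:]]+")[[1]][1]
        labels <- c(labels, substring(lab, 2L))
        i <- i + 1L
      }
      if (!length(labels)) {
        stop("malformed loop header (no column labels) at line ", i)
      }
      rows <- list()
      while (i <= length(lines) && lines[i] != "" &&
             !startsWith(lines[i], "data_") && lines[i] != "loop_") {
        cells <- strsplit(lines[i], "[[:space:]]+")[[1]]
        if (length(cells) != length(labels)) {
          stop("loop row with ", length(cells), " cells (expected ",
               length(labels), ") at line ", i)
        }
        rows[[length(rows) + 1L]] <- cells
        i <- i + 1L
      }
      m <- do.call(rbind, rows)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      if (is.null(m)) df <- as.data.frame(matrix(character(), 0,
                                                 length(labels)))
      names(df) <- labels
      df[] <- lapply(df, star_type_cell)
      flush_pairs()
      store_block(cur_name, list(type = "loop", data = df))
    } else if (startsWith(ln, "_")) {
      parts <- strsplit(ln, "[[:space:]]+")[[1]]
      key <- substring(parts[1], 2L)
      val <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else ""
      cur_pairs[[key]] <- star_type_cell(val)
      i <- i + 1L
    } else {
      stop("unparseable STAR content at line ", i, ": '", ln, "'")
    }
  }
  flush_pairs()
  structure(doc, class = "star_document")
}

star_format_cell <- function(x) {
  if (is.integer(x)) return(format(x, scientific = FALSE, trim = TRUE))
  if (is.numeric(x)) {
    return(vapply(x, function(v) {
      if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
        sprintf("%.6f", v)
      } else {
        format(v, digits = 10, scientific = TRUE, trim = TRUE)
      }
    }, character(1)))
  }
  as.character(x)
}

#' Write a STAR document
#'
#' Inverse of [read_star()]: block order, column order and numeric values
#' (to at least 6 significant digits) survive the round trip.
#'
#' @param doc a `star_document` (or plain named list of blocks)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_star <- function(doc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# written by pseudotomo", con)
  for (nm in names(doc)) {
    blk <- doc[[nm]]
    writeLines(c("", paste0("data_", nm), ""), con)
    if (identical(blk$type, "pairs")) {
      for (k in names(blk$values)) {
        writeLines(paste0("_", k, "    ",
                          star_format_cell(blk$values[[k]])), con)
      }
    } else if (identical(blk$type, "loop")) {
      df <- blk$data
      writeLines("loop_", con)
      writeLines(paste0("_", names(df), " #", seq_along(df)), con)
      if (nrow(df)) {
        cols <- lapply(df, star_format_cell)
        cols <- lapply(cols, formatC, flag = "-")
        writeLines(do.call(paste, cols), con)
      }
    } else {
      stop("unknown STAR block type for block '", nm, "'")
    }
  }
  invisible(path)
}
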