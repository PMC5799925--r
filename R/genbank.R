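## Minimal GenBank flat-file reader and writer.
##
## Only what the pipeline needs is parsed: per record (replicon) the LOCUS
## name and every CDS feature carrying a /translation. Locations of the
## forms start..end, complement(start..end), and join()/order() wrappers
## (collapsed to their overall extent) are supported; partial-end markers
## (< and >) are stripped. GenBank coordinates are 1-based inclusive and
## converted to the internal 0-based half-open convention.

parse_genbank_location <- function(loc) {
  strand <- if (grepl("complement", loc, fixed = TRUE)) "-" else "+"
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
  if (length(nums) < 2) return(NULL)
  nums <- as.numeric(nums)
  list(start1 = min(nums), end1 = max(nums), strand = strand)
}

## Returns a list of records; each record is a list(replicon, features)
## where features is a list of list(location, qualifiers).
read_genbank_records <- function(path) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec_breaks <- c(0L, which(lines == "//"))
  records <- list()
  for (r in seq_len(length(rec_breaks) - 1L)) {
    block <- lines[(rec_breaks[r] + 1L):(rec_breaks[r + 1L] - 1L)]
    if (!length(block)) next
    locus_line <- grep("^LOCUS", block, value = TRUE)
    replicon <- if (length(locus_line)) {
      strsplit(trimws(sub("^LOCUS", "", locus_line[1])), "\\s+")[[1]][1]
    } else {
      sprintf("record_%d", r)
    }
    fstart <- grep("^FEATURES", block)
    if (!length(fstart)) {
      records[[length(records) + 1L]] <- list(replicon = replicon,
                                              features = list())
      next
    }
    fend <- grep("^(ORIGIN|CONTIG|BASE COUNT)", block)
    fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(block)
    flines <- block[(fstart[1] + 1L):fend]
    ## a new feature starts at column 6 (5 leading spaces, then a key)
    is_key <- grepl("^ {5}\\S", flines)
    starts <- which(is_key)
    feats <- list()
    for (i in seq_along(starts)) {
      from <- starts[i]
      to <- if (i < length(starts)) starts[i + 1L] - 1L else length(flines)
      chunk <- flines[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1])
      body <- trimws(c(sub("^ {5}\\S+\\s*", "", chunk[1]), chunk[-1]))
      ## location: leading lines up to the first qualifier (starts with /)
      qstart <- grep("^/", body)
      loc_lines <- if (length(qstart)) body[seq_len(qstart[1] - 1L)] else body
      location <- paste(loc_lines, collapse = "")
      quals <- list()
      if (length(qstart)) {
        qlines <- body[qstart[1]:length(body)]
        qbreaks <- grep("^/", qlines)
        for (j in seq_along(qbreaks)) {
          qfrom <- qbreaks[j]
          qto <- if (j < length(qbreaks)) qbreaks[j + 1L] - 1L else length(qlines)
          qtxt <- paste(qlines[qfrom:qto], collapse = "")
          qname <- sub("^/([^=]+)=?.*$", "\\1", qtxt)
          qval <- if (grepl("=", qtxt, fixed = TRUE)) {
            gsub('^"|"$', "", sub("^/[^=]+=", "", qtxt))
          } else TRUE
          quals[[qname]] <- qval
        }
      }
      feats[[length(feats) + 1L]] <- list(key = key, location = location,
                                          qualifiers = quals)
    }
    records[[length(records) + 1L]] <- list(replicon = replicon,
                                            features = feats)
  }
  records
}

## Write one strain's genes (a data.table ordered by replicon/index) as a
## GenBank flat file. Feature annotation only: no nucleotide sequence is
## emitted (the pipeline works from protein translations and gene order).
write_genbank <- function(genes, path) {
  stopifnot(length(unique(genes$strain)) == 1L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rep_id in unique(genes$replicon_id)) {
    gr <- genes[genes$replicon_id == rep_id, ]
    gr <- gr[order(gr$index), ]
    seq_len_nt <- max(gr$end)
    writeLines(sprintf("LOCUS       %s  %d bp    DNA    linear  BCT",
                       rep_id, seq_len_nt), con)
    writeLines(sprintf("DEFINITION  synthetic genome of strain %s.",
                       gr$strain[1]), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", seq_len_nt), con)
    writeLines(sprintf('                     /organism="%s"', gr$strain[1]),
               con)
    for (i in seq_len(nrow(gr))) {
      loc <- sprintf("%d..%d", gr$start[i] + 1L, gr$end[i])
      if (gr$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf('                     /locus_tag="%s"',
                         gr$locus_tag[i]), con)
      writeLines(sprintf('                     /product="%s"',
                         gr$product[i]), con)
      tr <- gr$protein[i]
      from <- seq(1, nchar(tr), 44)
      chunks <- substring(tr, from, pmin(from + 43, nchar(tr)))
      chunks[1] <- paste0('/translation="', chunks[1])
      chunks[length(chunks)] <- paste0(chunks[length(chunks)], '"')
      for (ch in chunks) {
        writeLines(sprintf("                     %s", ch), con)
      }
    }
    writeLines("ORIGIN", con)
    writeLines("//", con)
  }
  invisible(path)
}
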