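# Minimal DICOM codec, Explicit VR Little Endian only, covering the tags an
# RT-Plan (beam / control-point / MLC-position sequences) and an RT-Dose
# (grid geometry, scaling, pixel data) need. Kept internal; the exported
# surface is readRtplan()/readRtdose() and the fixture writers.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
.SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.raw_u16 <- function(x) {
  x <- as.integer(x)
  as.raw(rbind(bitwAnd(x, 255L), bitwShiftR(x, 8L)))
}
.raw_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
               (x %/% 16777216) %% 256))
}
.rd_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
.rd_u32 <- function(raw, pos) {
  as.numeric(as.integer(raw[pos])) + 256 * as.integer(raw[pos + 1L]) +
    65536 * as.integer(raw[pos + 2L]) + 16777216 * as.integer(raw[pos + 3L])
}

.dcm_text <- function(s, padchar = " ") {
  r <- charToRaw(paste(s, collapse = "\\"))
  if (length(r) %% 2L) r <- c(r, if (padchar == "nul") as.raw(0L) else charToRaw(padchar))
  r
}
.dcm_ds <- function(x) .dcm_text(sprintf("%.10g", as.numeric(x)))
.dcm_is <- function(x) .dcm_text(sprintf("%d", as.integer(x)))

.dcm_elem <- function(group, elem, vr, value) {
  tag <- c(.raw_u16(group), .raw_u16(elem))
  if (vr %in% .LONG_VRS)
    c(tag, charToRaw(vr), as.raw(c(0L, 0L)), .raw_u32(length(value)), value)
  else
    c(tag, charToRaw(vr), .raw_u16(length(value)), value)
}
.dcm_item <- function(content) {
  c(.raw_u16(0xFFFE), .raw_u16(0xE000), .raw_u32(length(content)), content)
}
.dcm_sq <- function(group, elem, items) {
  .dcm_elem(group, elem, "SQ", do.call(c, items))
}

.dcm_uid <- function(suffix) {
  # private-use style UID root for synthetic objects
  paste0("2.25.", suffix)
}

.dcm_file <- function(sop_class, sop_instance, dataset) {
  meta <- c(
    .dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .dcm_elem(0x0002, 0x0002, "UI", .dcm_text(sop_class, "nul")),
    .dcm_elem(0x0002, 0x0003, "UI", .dcm_text(sop_instance, "nul")),
    .dcm_elem(0x0002, 0x0010, "UI", .dcm_text(.TS_EXPLICIT_LE, "nul")),
    .dcm_elem(0x0002, 0x0012, "UI", .dcm_text(.dcm_uid("987654321"), "nul")))
  c(as.raw(rep(0L, 128L)), charToRaw("DICM"),
    .dcm_elem(0x0002, 0x0000, "UL", .raw_u32(length(meta))),
    meta, dataset)
}

# ---- parser -------------------------------------------------------------

.dcm_key <- function(group, elem) sprintf("%04X%04X", group, elem)

# parse a run of explicit-VR-LE elements in raw[pos..end]; returns a named
# list tag -> list(vr, value-raw or items) plus the final position
.dcm_parse_elements <- function(raw, pos, end) {
  out <- list()
  while (pos <= end - 7L) {
    group <- .rd_u16(raw, pos); elem <- .rd_u16(raw, pos + 2L)
    if (group == 0xFFFE) { # stray delimiter (end of undefined-length item)
      pos <- pos + 8L
      if (elem == 0xE00D || elem == 0xE0DD) break
      next
    }
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- .rd_u32(raw, pos + 8L)
      body <- pos + 12L
    } else {
      len <- .rd_u16(raw, pos + 6L)
      body <- pos + 8L
    }
    key <- .dcm_key(group, elem)
    if (vr == "SQ") {
      sq_end <- if (len == 4294967295) end else body + len - 1L
      items <- list()
      ipos <- body
      while (ipos <= sq_end - 7L) {
        ig <- .rd_u16(raw, ipos); ie <- .rd_u16(raw, ipos + 2L)
        ilen <- .rd_u32(raw, ipos + 4L)
        ipos <- ipos + 8L
        if (ig == 0xFFFE && ie == 0xE0DD) break
        if (!(ig == 0xFFFE && ie == 0xE000))
          stop("malformed DICOM sequence item")
        if (ilen == 4294967295) {
          parsed <- .dcm_parse_elements(raw, ipos, sq_end)
        } else {
          parsed <- .dcm_parse_elements(raw, ipos, ipos + ilen - 1L)
          parsed$pos <- ipos + ilen
        }
        items[[length(items) + 1L]] <- parsed$elements
        ipos <- parsed$pos
      }
      out[[key]] <- list(vr = "SQ", items = items)
      pos <- if (len == 4294967295) ipos else sq_end + 1L
    } else {
      out[[key]] <- list(vr = vr,
                         value = if (len > 0) raw[body:(body + len - 1L)] else raw(0))
      pos <- body + len
    }
  }
  list(elements = out, pos = pos)
}

.dcm_read <- function(path) {
  n <- file.info(path)$size
  raw <- readBin(path, "raw", n = n)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  meta <- .dcm_parse_elements(raw, 133L, length(raw))
  ts <- .dcm_string(meta$elements[[.dcm_key(0x0002, 0x0010)]])
  if (!identical(ts, .TS_EXPLICIT_LE))
    stop("unsupported transfer syntax (only Explicit VR Little Endian): ", ts)
  # meta group ends where group changes from 0002; reparse dataset from there
  glen <- .rd_u32(raw, 133L + 8L) # (0002,0000) UL value
  ds_start <- 133L + 12L + glen
  .dcm_parse_elements(raw, ds_start, length(raw))$elements
}

.dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  s <- rawToChar(el$value[el$value != as.raw(0L)])
  trimws(s)
}
.dcm_numeric <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(.dcm_string(el), "\\", fixed = TRUE)[[1]])
}
.dcm_int <- function(el) {
  v <- .dcm_numeric(el)
  if (is.null(v)) NULL else as.integer(v)
}
.dcm_u16vec <- function(el) {
  if (is.null(el)) return(NULL)
  v <- el$value
  .rd_u16(v, seq(1L, length(v), by = 2L))
}
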