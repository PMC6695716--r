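#' Decode a WaveFormData hex stream into frames of 16-bit samples
#'
#' The dialect: whitespace-separated tokens where `FF` opens a new frame and
#' every 4-hex-digit token is one big-endian 16-bit sample appended to the
#' current frame. Samples before any `FF`, or tokens of any other shape,
#' fail the parse — except that the final token of a stream may carry an
#' incomplete trailing word (a transfer truncation); its complete leading
#' words are kept and the remainder is dropped, with the result flagged via
#' the `truncated` attribute.
#'
#' @param text The WaveFormData payload as a single string.
#' @return List of integer vectors (one per frame), with attribute
#'   `truncated` (logical).
#' @export
parse_waveform_hex <- function(text) {
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens <- tokens[tokens != ""]
  frames <- list()
  current <- NULL
  truncated <- FALSE
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (toupper(tok) == "FF") {
      if (!is.null(current)) frames[[length(frames) + 1L]] <- current
      current <- integer(0)
      next
    }
    if (!grepl("^[0-9A-Fa-f]+$", tok)) {
      abort(sprintf("token %d ('%s') is not hexadecimal", i, tok),
            class = "coilrate_parse")
    }
    if (is.null(current)) {
      abort(sprintf("token %d ('%s') appears before any FF frame marker",
                    i, tok),
            class = "coilrate_parse")
    }
    if (nchar(tok) == 4L) {
      current <- c(current, strtoi(tok, 16L))
    } else if (i == length(tokens) && nchar(tok) > 4L) {
      # run-on final token: keep whole 16-bit words, drop the remainder
      nwords <- nchar(tok) %/% 4L
      words <- substring(tok, 4L * (seq_len(nwords) - 1L) + 1L,
                         4L * seq_len(nwords))
      current <- c(current, strtoi(words, 16L))
      if (nchar(tok) %% 4L != 0L) truncated <- TRUE
    } else {
      abort(sprintf("token %d ('%s') has length %d; expected FF or 4 hex digits",
                    i, tok, nchar(tok)),
            class = "coilrate_parse")
    }
  }
  if (!is.null(current)) frames[[length(frames) + 1L]] <- current
  attr(frames, "truncated") <- truncated
  frames
}

encode_waveform_hex <- function(frames) {
  paste(vapply(frames, function(fr) {
    paste(c("FF", sprintf("%04X", as.integer(fr))), collapse = " ")
  }, character(1)), collapse = " ")
}

xml_text1 <- function(doc, xpath) {
  node <- xml2::xml_find_first(doc, xpath)
  if (inherits(node, "xml_missing")) {
    abort(sprintf("required element <%s> is missing", basename(xpath)),
          class = "coilrate_parse")
  }
  xml2::xml_text(node)
}

#' Parse a RestingECG XML record
#'
#' Reads the RestingECG dialect: patient metadata, waveform description, and
#' per-lead amplitude scale, CRC-32 field and hex-encoded waveform frames.
#' The stored CRC is kept as read; recomputation/comparison is a separate
#' step ([verify_lead_crc()]) so a truncated or corrupted payload still
#' parses.
#'
#' @param x Path to an XML file, or an XML string/`xml2` document.
#' @return Object of class `resting_ecg`: patient fields, `waveform_type`,
#'   `number_of_leads`, `sample_type`, `sample_base` (Hz), `battery`, and
#'   `leads` — a list with `amplitude_units_per_bit`, `lead_id`, `crc32`,
#'   `frames`, `truncated`.
#' @export
parse_resting_ecg_xml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  if (xml2::xml_name(doc) != "RestingECG") {
    abort("root element is not <RestingECG>", class = "coilrate_parse")
  }
  lead_nodes <- xml2::xml_find_all(doc, ".//Waveform/LeadData")
  if (length(lead_nodes) == 0) {
    abort("required element <LeadData> is missing", class = "coilrate_parse")
  }
  leads <- map(lead_nodes, function(nd) {
    wf <- parse_waveform_hex(xml_text1(nd, "./WaveFormData"))
    list(
      amplitude_units_per_bit = as.numeric(xml_text1(nd, "./LeadAmplitudeUnitsPerBit")),
      lead_id = as.integer(xml_text1(nd, "./LeadID")),
      crc32 = as.numeric(xml_text1(nd, "./LeadDataCRC32")),
      frames = wf,
      truncated = attr(wf, "truncated")
    )
  })
  rec <- structure(
    list(
      patient_id = xml_text1(doc, "/RestingECG/PatientID"),
      date_of_birth = xml_text1(doc, "/RestingECG/DateofBirth"),
      gender = xml_text1(doc, "/RestingECG/Gender"),
      waveform_type = xml_text1(doc, "/RestingECG/Waveform/WaveformType"),
      number_of_leads = as.integer(xml_text1(doc, "/RestingECG/Waveform/NumberofLeads")),
      sample_type = xml_text1(doc, "/RestingECG/Waveform/SampleType"),
      sample_base = as.integer(xml_text1(doc, "/RestingECG/Waveform/SampleBase")),
      battery = xml_text1(doc, "/RestingECG/Waveform/Battery"),
      leads = leads
    ),
    class = "resting_ecg"
  )
  if (rec$sample_base <= 0) abort("SampleBase must be positive",
                                  class = "coilrate_parse")
  rec
}

#' @export
print.resting_ecg <- function(x, ...) {
  cat(sprintf("<resting_ecg> %s (%s, b. %s): %s, %d lead(s) @ %d Hz\n",
              x$patient_id, x$gender, x$date_of_birth, x$waveform_type,
              x$number_of_leads, x$sample_base))
  for (ld in x$leads) {
    cat(sprintf("  lead %d: %d frames, %d samples, %.2f units/bit, CRC32 %.0f%s\n",
                ld$lead_id, length(ld$frames),
                sum(lengths(ld$frames)), ld$amplitude_units_per_bit,
                ld$crc32, if (isTRUE(ld$truncated)) " (payload truncated)" else ""))
  }
  invisible(x)
}

#' Write a RestingECG record back to XML
#'
#' Element names and nesting mirror the record dialect exactly (including
#' the `DateofBirth` / `NumberofLeads` spellings); waveform frames are
#' re-encoded as `FF`-delimited 4-digit hex words.
#'
#' @param record A `resting_ecg` object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_resting_ecg_xml <- function(record, path) {
  doc <- xml2::xml_new_root("RestingECG")
  add <- function(parent, name, value) {
    xml2::xml_add_child(parent, name, as.character(value))
  }
  add(doc, "PatientID", record$patient_id)
  add(doc, "DateofBirth", record$date_of_birth)
  add(doc, "Gender", record$gender)
  wf <- xml2::xml_add_child(doc, "Waveform")
  add(wf, "WaveformType", record$waveform_type)
  add(wf, "NumberofLeads", record$number_of_leads)
  add(wf, "SampleType", record$sample_type)
  add(wf, "SampleBase", record$sample_base)
  add(wf, "Battery", record$battery)
  for (ld in record$leads) {
    nd <- xml2::xml_add_child(wf, "LeadData")
    add(nd, "LeadAmplitudeUnitsPerBit", ld$amplitude_units_per_bit)
    add(nd, "LeadID", ld$lead_id)
    add(nd, "LeadDataCRC32", format(ld$crc32, scientific = FALSE))
    add(nd, "WaveFormData", encode_waveform_hex(ld$frames))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Verify stored lead CRCs against the decoded payload
#'
#' Recomputes CRC-32 over the big-endian byte serialization of each lead's
#' concatenated frame samples and compares it with the stored
#' `LeadDataCRC32`. Mismatches are reported, not raised: a record whose
#' printed payload is truncated will parse but fail verification.
#'
#' @param record A `resting_ecg` object.
#' @return Tibble with `lead_id`, `stored`, `computed`, `ok`, `truncated`.
#' @export
verify_lead_crc <- function(record) {
  map_dfr(record$leads, function(ld) {
    computed <- crc32(samples_to_bytes(unlist(ld$frames)))
    tibble(lead_id = ld$lead_id, stored = ld$crc32, computed = computed,
           ok = computed == ld$crc32,
           truncated = isTRUE(ld$truncated))
  })
}

#' Waveform samples of one lead as a millivolt signal
#'
#' Concatenates the lead's frames and converts offset-binary 16-bit samples
#' to millivolts using the lead's amplitude scale (units per bit,
#' interpreted as microvolts per count around the 32768 midscale).
#'
#' @param record A `resting_ecg` object.
#' @param lead Lead number (index into `record$leads`).
#' @return A `coil_signal` in millivolts at `sample_base` Hz.
#' @export
lead_signal <- function(record, lead = 1L) {
  if (lead < 1 || lead > length(record$leads)) abort("no such lead")
  ld <- record$leads[[lead]]
  samples <- unlist(ld$frames)
  mv <- (samples - 32768) * ld$amplitude_units_per_bit / 1000
  as_signal(mv, fs = record$sample_base, unit = "millivolt")
}
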