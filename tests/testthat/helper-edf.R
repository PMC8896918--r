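# Minimal EDF writer used only to exercise the package's EDF reader.
# Produces a synthetic single-record EDF file with int16 samples and the
# standard physical/digital calibration fields.
write_test_edf <- function(path, channels, fs, record_dur = NULL,
                           phys_min = -500, phys_max = 500) {
  ns <- length(channels)
  nsamp <- lengths(channels)
  if (is.null(record_dur)) record_dur <- nsamp[1] / fs
  pad <- function(s, w) sprintf(paste0("%-", w, "s"), substr(s, 1, w))
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8)                                   # version
  wr("test patient", 80)
  wr("test recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(as.character(256 * (ns + 1)), 8)          # header bytes
  wr("", 44)
  wr("1", 8)                                   # one data record
  wr(format(record_dur), 8)
  wr(as.character(ns), 4)
  each <- function(vals, w) for (v in vals) wr(v, w)
  each(names(channels), 16)
  each(rep("", ns), 80)                        # transducer
  each(rep("uV", ns), 8)
  each(rep(format(phys_min), ns), 8)
  each(rep(format(phys_max), ns), 8)
  each(rep("-32768", ns), 8)
  each(rep("32767", ns), 8)
  each(rep("", ns), 80)                        # prefiltering
  each(as.character(nsamp), 8)
  each(rep("", ns), 32)
  gain <- (phys_max - phys_min) / (32767 - (-32768))
  for (ch in channels) {
    dig <- as.integer(round((ch - phys_min) / gain + (-32768)))
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}
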