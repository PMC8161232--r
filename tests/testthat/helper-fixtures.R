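# Shared fixture builders. All fixtures are generated in code; nothing is
# stored on disk.

two_burst_layout <- function() {
  data.frame(kind = c("tone", "silence", "tone"),
             duration_s = c(1, 0.8, 1),
             amplitude = c(0.5, 0, 0.5),
             frequency = 440)
}

# minimal valid emotion row(s)
emotion_rows <- function(joy, sorrow, calmness, excitement, anger = 0,
                         subject_id = "s1", session_id = "v1") {
  n <- max(lengths(list(joy, sorrow, calmness, excitement)))
  data.frame(subject_id = subject_id, session_id = session_id,
             utterance_index = seq_len(n), anger = anger, joy = joy,
             sorrow = sorrow, calmness = calmness, excitement = excitement)
}

# writes a stereo 16-bit PCM WAV: constant left/right amplitudes
write_stereo_wav <- function(path, left, right, n = 1000L,
                             sample_rate = 11025L) {
  qs <- function(a) as.integer(round(max(-1, min(1, a)) * 32768))
  inter <- as.integer(rbind(rep(qs(left), n), rep(qs(right), n)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(inter) * 2L), con, size = 4L,
           endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")        # stereo
  writeBin(sample_rate, con, size = 4L, endian = "little")
  writeBin(sample_rate * 4L, con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(inter) * 2L, con, size = 4L, endian = "little")
  writeBin(inter, con, size = 2L, endian = "little")
  invisible(path)
}

# writes a WAV with an arbitrary format tag (for non-PCM error tests)
write_wav_with_format <- function(path, format_tag = 3L, n = 100L,
                                  sample_rate = 11025L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n * 2L), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(as.integer(format_tag), con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(sample_rate, con, size = 4L, endian = "little")
  writeBin(sample_rate * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n * 2L, con, size = 4L, endian = "little")
  writeBin(integer(n), con, size = 2L, endian = "little")
  invisible(path)
}

# exhaustive Mann-Whitney pair-count oracle for AUC
auc_pair_oracle <- function(pos, neg) {
  wins <- outer(pos, neg, ">")
  ties <- outer(pos, neg, "==")
  (sum(wins) + 0.5 * sum(ties)) / (length(pos) * length(neg))
}

# exhaustive Youden scan oracle over all midpoint cutpoints
youden_oracle <- function(pos, neg) {
  u <- sort(unique(c(pos, neg)))
  cuts <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  max(vapply(cuts, function(cc) mean(pos > cc) + mean(neg <= cc) - 1,
             numeric(1)))
}
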