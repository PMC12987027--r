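# Byte-exact codec behaviour: layout, checksums, rejects, resynchronization.

test_that("encoded packet has the documented layout and checksum", {
  p <- encode_packet(rep(0L, 8), 0L)
  expect_length(p$bytes, 40L)
  expect_identical(p$bytes[1:3], as.raw(c(0xAA, 0xFF, 0xF1)))
  expect_identical(as.integer(p$bytes[4]), 0x22L)
  expect_true(all(p$bytes[5:38] == as.raw(0)))
  # all-zero payload: checksum1 forced by header arithmetic
  expect_equal(as.integer(p$bytes[39]), (0xAA + 0xFF + 0xF1 + 0x22) %% 256)
  expect_identical(p$bytes[39], as.raw(0xBC))
})

test_that("checksum1 matches an independent byte-sum oracle", {
  p <- encode_packet(c(1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L), 0x0001L)
  # oracle: plain sum over the first 38 bytes, written before the codec
  expect_identical(as.integer(p$bytes[39]),
                   sum(as.integer(p$bytes[1:38])) %% 256L)
  set.seed(11)
  for (i in 1:20) {
    s <- sample.int(2^24, 8) - 2^23
    fl <- sample.int(65536, 1) - 1L
    b <- encode_packet(s, fl)$bytes
    expect_length(b, 40L)
    expect_identical(as.integer(b[39]), sum(as.integer(b[1:38])) %% 256L)
  }
})

test_that("checksum2 accumulates checksum1 over the stream", {
  set.seed(3)
  counts <- matrix(sample(-1000:1000, 40), ncol = 8)
  stream <- encode_stream(counts)
  frames <- matrix(stream, nrow = 40)
  cs1 <- as.integer(frames[39, ])
  expect_identical(as.integer(frames[40, ]), cumsum(cs1) %% 256L)
  # threading state through encode_packet agrees with encode_stream
  st <- 0L
  for (i in seq_len(nrow(counts))) {
    p <- encode_packet(counts[i, ], 0L, checksum2_state = st)
    expect_identical(p$bytes, frames[, i])
    st <- p$checksum2_state
  }
})

test_that("decode inverts encode and rejects are typed values", {
  set.seed(7)
  for (i in 1:25) {
    s <- as.integer(sample(-2^23:(2^23 - 1), 8))
    fl <- sample.int(65536, 1) - 1L
    d <- decode_packet(encode_packet(s, fl)$bytes)
    expect_true(d$ok)
    expect_identical(d$samples, s)
    expect_identical(d$leadoff, as.logical(rawToBits(as.raw(fl %% 256)))[1:8])
    expect_identical(as.integer(d$flag_bytes[2]), fl %/% 256L)  # byte 2 verbatim
  }
  b <- valid_packet_bytes()
  b0 <- b; b0[1] <- as.raw(0)
  expect_identical(decode_packet(b0)$reason, "bad_header")
  b1 <- b; b1[4] <- as.raw(0x21)
  expect_identical(decode_packet(b1)$reason, "bad_length")
  expect_error(encode_packet(c(rep(0, 7), 2^31), 0L), "int32")
})

test_that("any single-byte corruption in the checksummed span is detected", {
  b <- valid_packet_bytes()
  for (pos in 1:39) {
    for (v in c(0x01, 0x80, 0xFF)) {
      bad <- b
      bad[pos] <- xor(bad[pos], as.raw(v))
      d <- decode_packet(bad)
      expect_false(d$ok, info = sprintf("pos %d xor %02x", pos, v))
    }
  }
})

test_that("resynchronization recovers frames and counts discards", {
  set.seed(21)
  counts <- matrix(sample(-100:100, 5 * 8, TRUE), ncol = 8)
  stream <- encode_stream(counts)
  s <- resync_stream(stream)
  expect_identical(nrow(s$counts), 5L)
  expect_identical(s$discard_count, 0L)
  expect_identical(unname(s$counts), unname(counts))

  # 7 junk bytes ahead of one valid packet
  one <- valid_packet_bytes()
  s2 <- resync_stream(c(as.raw(1:7), one))
  expect_identical(nrow(s2$counts), 1L)
  expect_identical(s2$discard_count, 7L)

  # junk containing a spurious sync word with a failing checksum
  junk <- c(as.raw(c(0xAA, 0xFF, 0xF1, 0x22)), as.raw(rep(0x55, 36)))
  s3 <- resync_stream(c(junk, stream))
  expect_identical(nrow(s3$counts), 5L)
  expect_identical(s3$discard_count, 40L)
  expect_identical(unname(s3$counts), unname(counts))
})

test_that("resync survives any junk prefix up to one frame length", {
  set.seed(5)
  counts <- matrix(sample(-100:100, 3 * 8, TRUE), ncol = 8)
  stream <- encode_stream(counts)
  for (k in c(0L, 1L, 13L, 39L)) {
    junk <- as.raw(sample(0:255, k, TRUE))
    s <- resync_stream(c(junk, stream))
    expect_identical(nrow(s$counts), 3L)
    expect_identical(unname(s$counts), unname(counts))
    expect_identical(s$discard_count, k)
  }
})

test_that("stream files and the frame-table export round-trip", {
  counts <- matrix(c(1L, 2L, 3L, -4L, 5L, -6L, 7L, 8L), ncol = 8)
  stream <- encode_stream(counts, leadoff_flags = 5L)  # channels I and V1 off
  path <- withr::local_tempfile(fileext = ".bin")
  write_stream_file(stream, path)
  s <- resync_stream(read_stream_file(path))
  expect_identical(unname(s$counts), unname(counts))
  tb <- tidy(s)
  expect_identical(names(tb)[1:9], c("frame", "I", "II", paste0("V", 1:6)))
  expect_true(tb$off_I[1] && tb$off_V1[1] && !tb$off_II[1])
  expect_error(read_stream_file(withr::local_tempfile()), "missing")
})
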