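test_that("record capacity follows the SBD budget arithmetic", {
  expect_equal(max_records(1), 80)   # floor(320 / 4)
  expect_equal(max_records(4), 45)   # floor(320 / 7)
  expect_equal(max_records(317), 1)
  expect_error(max_records(0), ">= 1")
})

test_that("header layout and record offsets match the wire format", {
  sch <- quant_scheme()
  rec <- data.frame(cell = c(7, 300), time = c(120, 60), chl = c(1, 2))
  msg <- encode_message(1, 9, 78.95, 11.95, rec, sch)
  expect_equal(length(msg), 10 + 2 * 4)
  expect_equal(as.integer(msg[1]), 1)                       # message ID at 0
  expect_equal(as.integer(msg[2]), 9)                       # vehicle ID at 1
  expect_equal(readBin(msg[3:6], "numeric", size = 4, endian = "big"),
               78.95, tolerance = 1e-5)                     # lat at 2
  expect_equal(readBin(msg[7:10], "numeric", size = 4, endian = "big"),
               11.95, tolerance = 1e-5)                     # lon at 6
  # first record: data byte at 10, cell UInt16 big-endian at 11, time at 13
  expect_equal(as.integer(msg[12]) * 256 + as.integer(msg[13]), 7)
  expect_equal(as.integer(msg[14]), 2)                      # 120 s = 2 min
  # second record at 10 + n_d
  expect_equal(as.integer(msg[16]) * 256 + as.integer(msg[17]), 300)

  expect_equal(length(encode_message(1, 1, 0, 0, NULL, sch)), 10)
  expect_error(encode_message(1, 1, 0, 0,
                              data.frame(cell = 65536, time = 0, chl = 1), sch),
               "UInt16")
})

test_that("oversized queues are truncated to the newest records within 340 bytes", {
  sch <- quant_scheme()
  q <- data.frame(cell = 0:99, time = seq(6000, 60, by = -60), chl = 1:100)
  msg <- encode_message(1, 1, 0, 0, q, sch)
  expect_equal(length(msg), 330)   # 10 + 80 * 4
  expect_lte(length(msg), 340)
  dec <- decode_message(msg, sch)
  expect_equal(nrow(dec$records), 80)
  expect_equal(dec$records$cell, 0:79)   # the 80 newest (queue is newest-first)
})

test_that("messages round-trip exactly at code level under fuzzing", {
  set.seed(23)
  for (n_c in c(1L, 3L)) {
    sch <- quant_scheme(n_c = n_c)
    for (rep in 1:20) {
      m <- sample(0:max_records(n_c), 1)
      rec <- data.frame(cell = sample(0:65535, m, replace = TRUE),
                        time = sort(runif(m, 0, 15000), decreasing = TRUE))
      for (j in seq_len(n_c))
        rec[[paste0("v", j)]] <- rlnorm(m, 0, 2)
      msg <- encode_message(1, sample(0:255, 1), runif(1, -90, 90),
                            runif(1, -180, 180), rec, sch)
      expect_lte(length(msg), 340)
      expect_equal((length(msg) - 10) %% (3 + n_c), 0)
      dec <- decode_message(msg, sch)
      expect_equal(dec$records$cell, rec$cell)
      # re-encoding the decoded records reproduces the byte string
      rt <- dec$records[, c("cell", "time", paste0("chan", seq_len(n_c)))]
      msg2 <- encode_message(dec$header$message_id, dec$header$vehicle_id,
                             dec$header$lat, dec$header$lon, rt, sch)
      expect_identical(msg2, msg)
    }
  }
})

test_that("quantization hits its endpoints and error bound", {
  sch <- quant_scheme(log_min = log(0.01), log_max = log(100))
  expect_equal(encode_value(0.01, sch), 0L)
  expect_equal(encode_value(100, sch), 255L)
  expect_equal(encode_value(0.001, sch), 0L)    # clipped at the low end
  expect_equal(encode_value(1e5, sch), 255L)    # clipped at the high end
  set.seed(29)
  v <- rlnorm(2000, 0, 2)
  err <- abs(log(decode_value(encode_value(v, sch), sch)) -
             pmin(pmax(log(v), log(0.01)), log(100)))
  bound <- (log(100) - log(0.01)) / (2 * 255)
  expect_lte(max(err), bound + 1e-12)
})

test_that("malformed messages are rejected with diagnostics", {
  sch <- quant_scheme()
  msg <- encode_message(1, 1, 0, 0, data.frame(cell = 1, time = 0, chl = 1), sch)
  expect_error(decode_message(msg[1:8], sch), "header")
  expect_error(decode_message(msg[1:12], sch), "not a multiple")
  bad <- msg; bad[1] <- as.raw(77)
  expect_error(decode_message(bad, sch), "unknown message ID")
})

test_that("the hub relays other vehicles' data and positions", {
  sch <- quant_scheme()
  hub <- hub_state(sch)
  recA <- data.frame(cell = c(1, 2), time = c(600, 540), chl = c(2.0, 4.0))
  msgA <- encode_message(1, 1, 78.9, 11.9, recA, sch)
  exA <- hub_exchange(hub, msgA, 700)
  hub <- exA$hub
  # lone vehicle so far: empty data section, no positions
  expect_equal(length(exA$reply), 10)
  expect_equal(nrow(exA$positions), 0)

  msgB <- encode_message(1, 2, 78.8, 11.8, NULL, sch)
  exB <- hub_exchange(hub, msgB, 800)
  hub <- exB$hub
  dec <- decode_message(exB$reply, sch)
  expect_setequal(dec$records$cell, c(1, 2))
  expect_equal(exB$positions$vehicle, 1)
  expect_equal(exB$positions$lat, 78.9, tolerance = 1e-5)

  # a repeated exchange does not resend already-delivered records
  exB2 <- hub_exchange(hub, msgB, 900)
  hub <- exB2$hub
  expect_equal(nrow(decode_message(exB2$reply, sch)$records), 0)

  # newer report for the same cell supersedes the old one
  msgA2 <- encode_message(1, 1, 78.9, 11.9,
                          data.frame(cell = 5, time = 1200, chl = 1), sch)
  hub <- hub_exchange(hub, msgA2, 1300)$hub
  msgA3 <- encode_message(1, 1, 78.9, 11.9,
                          data.frame(cell = 5, time = 2400, chl = 9), sch)
  hub <- hub_exchange(hub, msgA3, 2500)$hub
  kept <- hub$store[hub$store$cell == 5, ]
  expect_equal(nrow(kept), 1)
  expect_equal(kept$time, decode_time(encode_time(2400, sch), sch))

  # undecodable input is logged and dropped, with an empty reply
  expect_warning(bad <- hub_exchange(hub, as.raw(c(1, 2, 3)), 0), "undecodable")
  expect_equal(length(bad$reply), 10)
})

test_that("per-vehicle grids reach eventual consistency after an exchange round", {
  sch <- quant_scheme()
  cfg <- small_volume()
  hub <- hub_state(sch)
  set.seed(41)
  grids <- list()
  # three vehicles each sample a disjoint region and report
  for (v in 1:3) {
    gs <- grid_state(cfg)
    n <- 40
    batch <- data.frame(x = runif(n, (v - 1) * 200, (v - 1) * 200 + 199),
                        y = runif(n, 0, 800), z = runif(n, 0, 40),
                        time = runif(n, 0, 500), chl = rlnorm(n))
    grids[[v]] <- segment_measurements(batch, gs)
  }
  codes <- function(gs) {
    cells <- grid_cells(gs)
    data.frame(cell = cells$cell, code = encode_value(cells$chan1, sch))
  }
  merge_reply <- function(gs, reply) {
    dec <- decode_message(reply, sch)
    for (k in seq_len(nrow(dec$records))) {
      ci <- dec$records$cell[k] + 1L
      if (is.na(gs$time[ci]) || dec$records$time[k] > gs$time[ci]) {
        gs$time[ci] <- dec$records$time[k]
        gs$value[ci, 1] <- dec$records$chan1[k]
      }
    }
    gs
  }
  # vehicles report only the cells they segmented themselves
  own <- lapply(grids, function(gs) {
    cells <- grid_cells(gs)
    rec <- data.frame(cell = cells$cell, time = cells$time, chl = cells$chan1)
    rec[order(-rec$time), ]
  })
  report <- function(v, t) {
    ex <- hub_exchange(hub, encode_message(1, v, 60, 5, own[[v]], sch), t)
    hub <<- ex$hub
    grids[[v]] <<- merge_reply(grids[[v]], ex$reply)
  }
  # two rounds with no new sampling in between: every vehicle ends up with
  # identical codes on every reported cell
  for (round in 1:2) for (v in 1:3) report(v, 1000 * round + v)
  c1 <- codes(grids[[1]]); c2 <- codes(grids[[2]]); c3 <- codes(grids[[3]])
  expect_equal(c1, c2)
  expect_equal(c2, c3)
})
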