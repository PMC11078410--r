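# Bandwidth-constrained grid-data exchange: binary cell-data messages under
# the 340-byte satellite short-burst-data (SBD) limit, and the operator hub
# that relays data and positions between vehicles.
#
# Wire format (all multi-byte fields big-endian / network order):
#   byte 0      message ID   UInt8   (1 = vehicle data report, 2 = hub reply)
#   byte 1      vehicle ID   UInt8
#   byte 2..5   latitude     IEEE single
#   byte 6..9   longitude    IEEE single
#   byte 10+k*n_d   ...      n_c quantized data bytes (UInt8 each)
#   byte 10+k*n_d+n_c        cell number, UInt16
#   byte 12+k*n_d+n_c        time, UInt8
# with record size n_d = 3 + n_c and k = 0 .. l_d-1.

SBD_LIMIT <- 340L
SBD_DRIVER_OVERHEAD <- 20L

#' Maximum cell records per message
#'
#' The SBD protocol caps a message at 340 bytes and the vehicle driver needs
#' 20 bytes of overhead, leaving 320 usable bytes; a record for one cell
#' takes `n_d = 3 + n_c` bytes, so up to `l_d = floor(320 / n_d)` records fit.
#'
#' @param n_c Number of data channels (>= 1).
#' @return Integer record capacity `l_d`.
#' @examples
#' max_records(1)  # 80
#' @export
max_records <- function(n_c) {
  if (n_c < 1) stop("n_c must be >= 1")
  as.integer((SBD_LIMIT - SBD_DRIVER_OVERHEAD) %/% (3L + as.integer(n_c)))
}

#' Quantization scheme for cell records
#'
#' Table-driven mapping between physical values and the single data byte per
#' channel, and between acquisition times and the single time byte.  Values
#' are quantized linearly on the log scale (the field is log-normal, so a
#' log grid spends its 256 codes where the data live); times are quantized
#' in fixed steps from the mission epoch, saturating at code 255.
#'
#' @param log_min,log_max Per-channel log-scale code range; scalars are
#'   recycled across channels.  Defaults cover 0.01 to 100 micrograms/L.
#' @param time_ref Mission epoch, seconds.
#' @param time_step Seconds per time code (default one minute).
#' @param n_c Number of channels.
#' @return An object of class `quant_scheme`.
#' @export
quant_scheme <- function(log_min = log(0.01), log_max = log(100),
                         time_ref = 0, time_step = 60, n_c = 1L) {
  log_min <- rep_len(log_min, n_c)
  log_max <- rep_len(log_max, n_c)
  if (any(log_max <= log_min)) stop("log_max must exceed log_min")
  if (time_step <= 0) stop("time_step must be positive")
  structure(list(log_min = log_min, log_max = log_max,
                 time_ref = time_ref, time_step = time_step,
                 n_c = as.integer(n_c)),
            class = "quant_scheme")
}

#' Quantize values to data bytes and back
#'
#' `decode_value(encode_value(v))` is within half a quantization step of the
#' clipped value on the log scale: the worst-case error is
#' `(log_max - log_min) / (2 * 255)`.
#'
#' @param v Physical values (positive).
#' @param scheme A `quant_scheme`.
#' @param channel Channel index (1-based).
#' @return `encode_value`: integer codes 0..255; `decode_value`: values.
#' @export
encode_value <- function(v, scheme, channel = 1L) {
  lo <- scheme$log_min[channel]; hi <- scheme$log_max[channel]
  lv <- pmin(pmax(log(pmax(v, .Machine$double.xmin)), lo), hi)
  as.integer(round(255 * (lv - lo) / (hi - lo)))
}

#' @rdname encode_value
#' @param code Integer codes 0..255.
#' @export
decode_value <- function(code, scheme, channel = 1L) {
  lo <- scheme$log_min[channel]; hi <- scheme$log_max[channel]
  exp(lo + (code / 255) * (hi - lo))
}

encode_time <- function(t, scheme) {
  as.integer(pmin(pmax(round((t - scheme$time_ref) / scheme$time_step), 0), 255))
}

decode_time <- function(code, scheme) {
  scheme$time_ref + code * scheme$time_step
}

uint16_bytes <- function(v) {
  v <- as.integer(v)
  if (any(v < 0 | v > 65535)) stop("cell number out of UInt16 range")
  as.raw(rbind(v %/% 256L, v %% 256L))
}

float32_bytes <- function(v) writeBin(as.numeric(v), raw(), size = 4, endian = "big")

read_float32 <- function(b) readBin(b, "numeric", n = length(b) %/% 4, size = 4, endian = "big")

#' Encode a cell-data message
#'
#' Builds a wire message from a header and a newest-first queue of cell
#' records.  If the queue holds more than `l_d` records the message is
#' truncated to the `l_d` newest; the emitted length is
#' `10 + min(nrow(records), l_d) * n_d`, never above 340 bytes.
#'
#' @param message_id,vehicle_id Header bytes (0..255).
#' @param lat,lon Header position, decimal degrees (IEEE single on the wire).
#' @param records Data.frame ordered newest first, with columns `cell`
#'   (0-based cell number), `time` (seconds), and one value column per
#'   channel (any remaining numeric columns, in channel order).  May have
#'   zero rows.
#' @param scheme A `quant_scheme`.
#' @return A raw vector.
#' @export
encode_message <- function(message_id, vehicle_id, lat, lon, records, scheme) {
  n_c <- scheme$n_c
  hdr <- c(as.raw(message_id), as.raw(vehicle_id),
           float32_bytes(lat), float32_bytes(lon))
  stopifnot(length(hdr) == 10)
  if (is.null(records) || nrow(records) == 0) return(hdr)
  ld <- max_records(n_c)
  if (nrow(records) > ld) records <- records[seq_len(ld), , drop = FALSE]
  val_cols <- setdiff(names(records), c("cell", "time"))
  if (length(val_cols) != n_c)
    stop("records carry ", length(val_cols), " channel(s), scheme expects ", n_c)
  m <- nrow(records)
  codes <- vapply(seq_len(n_c), function(j)
    encode_value(records[[val_cols[j]]], scheme, j), integer(m))
  codes <- matrix(codes, nrow = m)
  body <- vapply(seq_len(m), function(k) {
    c(as.raw(codes[k, ]),
      uint16_bytes(records$cell[k]),
      as.raw(encode_time(records$time[k], scheme)))
  }, raw(3L + n_c))
  msg <- c(hdr, as.vector(body))
  # data payload respects the 320-byte budget; the whole message stays
  # within the 340-byte SBD limit
  stopifnot(length(msg) - 10L <= SBD_LIMIT - SBD_DRIVER_OVERHEAD,
            length(msg) <= SBD_LIMIT)
  msg
}

#' Decode a cell-data message
#'
#' Inverse of [encode_message()].  Round-tripping is exact at the code level;
#' decoded values are within quantization tolerance of the originals.
#'
#' @param msg A raw vector.
#' @param scheme A `quant_scheme`.
#' @return A list with `header` (`message_id`, `vehicle_id`, `lat`, `lon`)
#'   and `records` (data.frame `cell`, `time`, `chan1`..., `code1`...).
#' @export
decode_message <- function(msg, scheme) {
  n_c <- scheme$n_c
  n_d <- 3L + n_c
  if (length(msg) < 10) stop("malformed message: shorter than the 10-byte header")
  if ((length(msg) - 10L) %% n_d != 0L)
    stop("malformed message: payload length ", length(msg) - 10L,
         " is not a multiple of the record size ", n_d)
  mid <- as.integer(msg[1])
  if (!mid %in% c(1L, 2L)) stop("unknown message ID ", mid)
  header <- list(message_id = mid,
                 vehicle_id = as.integer(msg[2]),
                 lat = read_float32(msg[3:6]),
                 lon = read_float32(msg[7:10]))
  m <- (length(msg) - 10L) %/% n_d
  if (m == 0) return(list(header = header, records = empty_records(n_c)))
  body <- matrix(as.integer(msg[-(1:10)]), nrow = n_d)
  codes <- matrix(body[seq_len(n_c), , drop = FALSE], nrow = n_c)
  cell <- body[n_c + 1L, ] * 256L + body[n_c + 2L, ]
  tcode <- body[n_c + 3L, ]
  rec <- data.frame(cell = cell, time = decode_time(tcode, scheme))
  for (j in seq_len(n_c)) rec[[paste0("chan", j)]] <- decode_value(codes[j, ], scheme, j)
  for (j in seq_len(n_c)) rec[[paste0("code", j)]] <- codes[j, ]
  rec$time_code <- tcode
  list(header = header, records = rec)
}

empty_records <- function(n_c) {
  rec <- data.frame(cell = integer(0), time = numeric(0))
  for (j in seq_len(n_c)) rec[[paste0("chan", j)]] <- numeric(0)
  for (j in seq_len(n_c)) rec[[paste0("code", j)]] <- integer(0)
  rec$time_code <- integer(0)
  rec
}

#' Hex dump of a wire message
#' @param msg A raw vector.
#' @param scheme Optional `quant_scheme`; when given, the decoded header and
#'   records are printed as well.
#' @return The hex string, invisibly when printing.
#' @export
msg_dump <- function(msg, scheme = NULL) {
  hex <- paste(format(msg), collapse = " ")
  cat(sprintf("[%d bytes] %s\n", length(msg), hex))
  if (!is.null(scheme)) {
    d <- decode_message(msg, scheme)
    cat(sprintf("message_id=%d vehicle_id=%d lat=%.5f lon=%.5f records=%d\n",
                d$header$message_id, d$header$vehicle_id,
                d$header$lat, d$header$lon, nrow(d$records)))
    if (nrow(d$records) > 0) print(utils::head(d$records, 10))
  }
  invisible(hex)
}

#' Create an empty operator-hub state
#'
#' The hub is the shore-side relay: it stores the newest record per
#' (reporting vehicle, cell), the reporters' last surface positions, and a
#' per-recipient delivery ledger so each reply forwards only data the
#' recipient has not yet received.
#'
#' @param scheme A `quant_scheme` shared by the whole fleet.
#' @return An object of class `hub_state`.
#' @export
hub_state <- function(scheme) {
  structure(list(scheme = scheme,
                 store = NULL,        # vehicle, cell, time, chanX..., seq
                 positions = NULL,    # vehicle, lat, lon, time
                 delivered = list(),  # per recipient: character keys
                 seq = 0L),
            class = "hub_state")
}

record_key <- function(df) paste(df$vehicle, df$cell, df$time, sep = ":")

#' One hub exchange with a surfaced vehicle
#'
#' Ingests a vehicle's data report, then replies with (a) the other
#' vehicles' last known surface positions (sent uncompressed — the fleet is
#' small, so this message is not size-constrained) and (b) the newest
#' not-yet-delivered cell records from the other vehicles, newest first,
#' truncated to the SBD record budget.  Records included in the reply are
#' marked delivered to this vehicle.  Undecodable input is dropped with a
#' warning and an empty reply.
#'
#' @param hub A `hub_state`.
#' @param msg Raw vector: the vehicle's report (message_id 1).
#' @param t Hub-side arrival time, seconds.
#' @return A list: `hub` (updated state), `reply` (raw vector, message_id 2),
#'   `positions` (data.frame `vehicle`, `lat`, `lon`, `time` of the others).
#' @export
hub_exchange <- function(hub, msg, t) {
  scheme <- hub$scheme
  dec <- tryCatch(decode_message(msg, scheme), error = function(e) {
    warning("undecodable report dropped: ", conditionMessage(e))
    NULL
  })
  if (is.null(dec)) {
    return(list(hub = hub,
                reply = encode_message(2, 0, 0, 0, NULL, scheme),
                positions = data.frame(vehicle = integer(0), lat = numeric(0),
                                       lon = numeric(0), time = numeric(0))))
  }
  vid <- dec$header$vehicle_id
  # store the reporter's surface position
  pos <- data.frame(vehicle = vid, lat = dec$header$lat,
                    lon = dec$header$lon, time = t)
  hub$positions <- rbind(hub$positions[hub$positions$vehicle != vid, , drop = FALSE], pos)
  # merge records, newest wins per (vehicle, cell)
  if (nrow(dec$records) > 0) {
    chan_cols <- grep("^chan", names(dec$records), value = TRUE)
    new <- cbind(data.frame(vehicle = vid), dec$records[, c("cell", "time", chan_cols)])
    new$seq <- hub$seq + seq_len(nrow(new))
    hub$seq <- hub$seq + nrow(new)
    st <- rbind(hub$store, new)
    # keep newest time (ties: latest arrival) per vehicle/cell
    st <- st[order(st$vehicle, st$cell, -st$time, -st$seq), , drop = FALSE]
    st <- st[!duplicated(st[, c("vehicle", "cell")]), , drop = FALSE]
    hub$store <- st
  }
  # build the reply: others' undelivered records, newest first
  key <- as.character(vid)
  seen <- hub$delivered[[key]]
  avail <- hub$store[hub$store$vehicle != vid, , drop = FALSE]
  if (!is.null(avail) && nrow(avail) > 0) {
    undel <- avail[!(record_key(avail) %in% seen), , drop = FALSE]
    undel <- undel[order(-undel$time, -undel$seq), , drop = FALSE]
    ld <- max_records(scheme$n_c)
    send <- utils::head(undel, ld)
  } else {
    send <- NULL
  }
  chan_cols <- paste0("chan", seq_len(scheme$n_c))
  reply_rec <- if (!is.null(send) && nrow(send) > 0)
    send[, c("cell", "time", chan_cols), drop = FALSE] else NULL
  reply <- encode_message(2, vid, 0, 0, reply_rec, scheme)
  if (!is.null(send) && nrow(send) > 0)
    hub$delivered[[key]] <- c(seen, record_key(send))
  others <- hub$positions[hub$positions$vehicle != vid, , drop = FALSE]
  if (is.null(others)) others <- data.frame(vehicle = integer(0), lat = numeric(0),
                                            lon = numeric(0), time = numeric(0))
  list(hub = hub, reply = reply, positions = others)
}
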