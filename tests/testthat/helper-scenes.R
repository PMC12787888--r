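# shared fixture builders

default_cam <- function(...) {
  args <- utils::modifyList(
    list(fx = 200, fy = 200, cx = 159.5, cy = 119.5,
         mount_height = 1.8, pitch_deg = 45),
    list(...))
  do.call(camera_model, args)
}

# depth frame filled with a constant raw value
const_depth <- function(value, width = 320, height = 240) {
  depth_frame(matrix(value, height, width))
}

# minimal detection data.frame in tlwh
make_dets <- function(frame, x, y, w, h, conf = 0.8, ...) {
  data.frame(frame = frame, id = -1L, x = x, y = y, w = w, h = h,
             conf = conf, ...)
}
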