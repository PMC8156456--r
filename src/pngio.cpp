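// Minimal PNG codec (8-bit grayscale / gray+alpha / RGB / RGBA, no
// interlace, no palette) so the package can read and write image files
// without an external imaging dependency.  Compression is delegated to
// zlib, which R itself links against.

#include <Rcpp.h>
#include <zlib.h>
#include <cstring>

using namespace Rcpp;

static const unsigned char PNG_SIG[8] = {137, 80, 78, 71, 13, 10, 26, 10};

static uint32_t be32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void put_be32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export]]
List cpp_png_decode(RawVector bytes) {
  const unsigned char* p = bytes.begin();
  const size_t n = bytes.size();
  if (n < 8 || std::memcmp(p, PNG_SIG, 8) != 0) stop("not a PNG file");
  size_t pos = 8;
  int W = 0, H = 0, bit_depth = 0, color_type = 0, interlace = 0;
  std::vector<unsigned char> idat;
  bool seen_ihdr = false, seen_iend = false;
  while (pos + 8 <= n && !seen_iend) {
    uint32_t len = be32(p + pos);
    const char* type = (const char*)(p + pos + 4);
    if (pos + 12 + (size_t)len > n) stop("truncated PNG chunk");
    const unsigned char* data = p + pos + 8;
    if (std::memcmp(type, "IHDR", 4) == 0) {
      if (len != 13) stop("bad IHDR");
      W = (int)be32(data);
      H = (int)be32(data + 4);
      bit_depth = data[8];
      color_type = data[9];
      interlace = data[12];
      seen_ihdr = true;
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), data, data + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      seen_iend = true;
    }
    pos += 12 + (size_t)len;
  }
  if (!seen_ihdr) stop("missing IHDR");
  if (bit_depth != 8) stop("only 8-bit PNG supported");
  if (interlace != 0) stop("interlaced PNG not supported");
  int ch;
  switch (color_type) {
    case 0: ch = 1; break;
    case 2: ch = 3; break;
    case 4: ch = 2; break;
    case 6: ch = 4; break;
    default: stop("palette PNG not supported");
  }
  const size_t rowbytes = (size_t)W * ch;
  const size_t rawlen = (size_t)H * (rowbytes + 1);
  std::vector<unsigned char> raw(rawlen);
  uLongf destlen = (uLongf)rawlen;
  int zrc = uncompress(raw.data(), &destlen, idat.data(), (uLong)idat.size());
  if (zrc != Z_OK || destlen != rawlen) stop("PNG inflate failed");
  // Unfilter in place into `img` (row-major byte order, channels interleaved)
  std::vector<unsigned char> img((size_t)H * rowbytes);
  for (int y = 0; y < H; ++y) {
    const unsigned char ft = raw[(size_t)y * (rowbytes + 1)];
    const unsigned char* src = raw.data() + (size_t)y * (rowbytes + 1) + 1;
    unsigned char* cur = img.data() + (size_t)y * rowbytes;
    const unsigned char* up =
        y > 0 ? img.data() + (size_t)(y - 1) * rowbytes : nullptr;
    for (size_t i = 0; i < rowbytes; ++i) {
      const int a = i >= (size_t)ch ? cur[i - ch] : 0;
      const int b = up ? up[i] : 0;
      const int c = (up && i >= (size_t)ch) ? up[i - ch] : 0;
      int v = src[i];
      switch (ft) {
        case 0: break;
        case 1: v += a; break;
        case 2: v += b; break;
        case 3: v += (a + b) / 2; break;
        case 4: v += paeth(a, b, c); break;
        default: stop("bad PNG filter type");
      }
      cur[i] = (unsigned char)(v & 0xff);
    }
  }
  // Emit as integer array dim c(H, W, ch), values 0..255.
  IntegerVector out((size_t)H * W * ch);
  out.attr("dim") = IntegerVector::create(H, W, ch);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      for (int c = 0; c < ch; ++c)
        out[(size_t)y + (size_t)H * (x + (size_t)W * c)] =
            img[(size_t)y * rowbytes + (size_t)x * ch + c];
  return List::create(_["pixels"] = out, _["width"] = W, _["height"] = H,
                      _["channels"] = ch);
}

static void write_chunk(std::vector<unsigned char>& out, const char* type,
                        const std::vector<unsigned char>& data) {
  put_be32(out, (uint32_t)data.size());
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  out.insert(out.end(), data.begin(), data.end());
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(4 + data.size()));
  put_be32(out, (uint32_t)crc);
}

// pixels: integer array dim c(H, W, ch), values 0..255; ch in {1, 2, 3, 4}.
// [[Rcpp::export]]
RawVector cpp_png_encode(IntegerVector pixels) {
  IntegerVector d = pixels.attr("dim");
  if (d.size() != 3) stop("pixels must be an H x W x C array");
  const int H = d[0], W = d[1], ch = d[2];
  int color_type;
  switch (ch) {
    case 1: color_type = 0; break;
    case 2: color_type = 4; break;
    case 3: color_type = 2; break;
    case 4: color_type = 6; break;
    default: stop("channels must be 1, 2, 3 or 4");
  }
  const size_t rowbytes = (size_t)W * ch;
  std::vector<unsigned char> raw((size_t)H * (rowbytes + 1));
  for (int y = 0; y < H; ++y) {
    raw[(size_t)y * (rowbytes + 1)] = 0;  // filter type none
    unsigned char* row = raw.data() + (size_t)y * (rowbytes + 1) + 1;
    for (int x = 0; x < W; ++x)
      for (int c = 0; c < ch; ++c) {
        int v = pixels[(size_t)y + (size_t)H * (x + (size_t)W * c)];
        if (v < 0) v = 0;
        if (v > 255) v = 255;
        row[(size_t)x * ch + c] = (unsigned char)v;
      }
  }
  uLongf bound = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(bound);
  int zrc = compress2(comp.data(), &bound, raw.data(), (uLong)raw.size(), 6);
  if (zrc != Z_OK) stop("PNG deflate failed");
  comp.resize(bound);

  std::vector<unsigned char> out(PNG_SIG, PNG_SIG + 8);
  std::vector<unsigned char> ihdr;
  put_be32(ihdr, (uint32_t)W);
  put_be32(ihdr, (uint32_t)H);
  ihdr.push_back(8);                  // bit depth
  ihdr.push_back((unsigned char)color_type);
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  write_chunk(out, "IHDR", ihdr);
  write_chunk(out, "IDAT", comp);
  write_chunk(out, "IEND", std::vector<unsigned char>());
  return RawVector(out.begin(), out.end());
}
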