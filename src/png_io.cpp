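// Minimal PNG codec (8-bit, non-interlaced, gray / RGB / RGBA) built directly
// on the system zlib. The installed R stack has no PNG package, and the
// dataset interface stores lesion images as PNG files, so the codec lives
// here. Writing always uses filter type 0; reading understands filters 0-4.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>

using namespace Rcpp;

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static uint32_t get_u32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void write_chunk(FILE* f, const char type[4],
                        const unsigned char* data, uint32_t len) {
  unsigned char hdr[8];
  hdr[0] = len >> 24; hdr[1] = (len >> 16) & 0xff;
  hdr[2] = (len >> 8) & 0xff; hdr[3] = len & 0xff;
  std::memcpy(hdr + 4, type, 4);
  std::fwrite(hdr, 1, 8, f);
  if (len) std::fwrite(data, 1, len, f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*)type, 4);
  if (len) crc = crc32(crc, data, len);
  unsigned char tail[4] = {
    (unsigned char)(crc >> 24), (unsigned char)((crc >> 16) & 0xff),
    (unsigned char)((crc >> 8) & 0xff), (unsigned char)(crc & 0xff)};
  std::fwrite(tail, 1, 4, f);
}

// [[Rcpp::export(name = ".cpp_write_png")]]
void cpp_write_png(std::string path, IntegerVector px) {
  IntegerVector d = px.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  if (C != 1 && C != 3 && C != 4) stop("channels must be 1, 3 or 4");
  const int bpp = C;
  std::vector<unsigned char> raw((size_t)H * (1 + (size_t)W * bpp));
  size_t pos = 0;
  for (int h = 0; h < H; ++h) {
    raw[pos++] = 0;  // filter type 0
    for (int w = 0; w < W; ++w)
      for (int c = 0; c < C; ++c) {
        int v = px[h + (R_xlen_t)H * (w + (R_xlen_t)W * c)];
        if (v < 0) v = 0;
        if (v > 255) v = 255;
        raw[pos++] = (unsigned char)v;
      }
  }
  uLongf clen = compressBound(raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), raw.size(), 6) != Z_OK)
    stop("zlib compression failed");
  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  static const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  std::fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)W);
  put_u32(ihdr, (uint32_t)H);
  ihdr.push_back(8);                                   // bit depth
  ihdr.push_back(C == 1 ? 0 : (C == 3 ? 2 : 6));       // color type
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  write_chunk(f, "IHDR", ihdr.data(), (uint32_t)ihdr.size());
  write_chunk(f, "IDAT", comp.data(), (uint32_t)clen);
  write_chunk(f, "IEND", nullptr, 0);
  std::fclose(f);
}

static int paeth(int a, int b, int c) {
  int p = a + b - c, pa = std::abs(p - a), pb = std::abs(p - b),
      pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export(name = ".cpp_read_png")]]
IntegerVector cpp_read_png(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s'", path.c_str());
  std::fseek(f, 0, SEEK_END);
  long n = std::ftell(f);
  std::fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf((size_t)n);
  if (std::fread(buf.data(), 1, n, f) != (size_t)n) {
    std::fclose(f);
    stop("short read on '%s'", path.c_str());
  }
  std::fclose(f);
  static const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  if (n < 8 || std::memcmp(buf.data(), sig, 8) != 0)
    stop("'%s' is not a PNG file", path.c_str());
  size_t pos = 8;
  int W = 0, H = 0, C = 0;
  std::vector<unsigned char> idat;
  while (pos + 8 <= (size_t)n) {
    uint32_t len = get_u32(&buf[pos]);
    const char* type = (const char*)&buf[pos + 4];
    const unsigned char* data = &buf[pos + 8];
    if (std::memcmp(type, "IHDR", 4) == 0) {
      W = (int)get_u32(data);
      H = (int)get_u32(data + 4);
      int depth = data[8], color = data[9], interlace = data[12];
      if (depth != 8) stop("only 8-bit PNGs are supported");
      if (interlace != 0) stop("interlaced PNGs are not supported");
      C = color == 0 ? 1 : (color == 2 ? 3 : (color == 6 ? 4 : -1));
      if (C < 0) stop("unsupported PNG color type %d", color);
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), data, data + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      break;
    }
    pos += 12 + (size_t)len;
  }
  if (W <= 0 || H <= 0 || idat.empty()) stop("malformed PNG");
  const int bpp = C;
  const size_t stride = 1 + (size_t)W * bpp;
  std::vector<unsigned char> raw((size_t)H * stride);
  uLongf rlen = raw.size();
  if (uncompress(raw.data(), &rlen, idat.data(), idat.size()) != Z_OK ||
      rlen != raw.size())
    stop("PNG inflate failed");
  // undo per-scanline filtering in place (into `img`)
  std::vector<unsigned char> img((size_t)H * W * bpp);
  for (int h = 0; h < H; ++h) {
    const unsigned char ft = raw[h * stride];
    const unsigned char* src = &raw[h * stride + 1];
    unsigned char* dst = &img[(size_t)h * W * bpp];
    const unsigned char* up = h > 0 ? &img[(size_t)(h - 1) * W * bpp] : nullptr;
    for (int i = 0; i < W * bpp; ++i) {
      int a = i >= bpp ? dst[i - bpp] : 0;
      int b = up ? up[i] : 0;
      int c = (up && i >= bpp) ? up[i - bpp] : 0;
      int v = src[i];
      switch (ft) {
        case 0: break;
        case 1: v += a; break;
        case 2: v += b; break;
        case 3: v += (a + b) / 2; break;
        case 4: v += paeth(a, b, c); break;
        default: stop("unsupported PNG filter type %d", ft);
      }
      dst[i] = (unsigned char)(v & 0xff);
    }
  }
  IntegerVector out((R_xlen_t)H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  for (int h = 0; h < H; ++h)
    for (int w = 0; w < W; ++w)
      for (int c = 0; c < C; ++c)
        out[h + (R_xlen_t)H * (w + (R_xlen_t)W * c)] =
          img[((size_t)h * W + w) * bpp + c];
  return out;
}
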