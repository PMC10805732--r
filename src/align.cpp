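#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Banded Needleman-Wunsch with affine gaps (Gotoh, three states).
// A gap of length k costs gap_open + gap_ext * k, matching the BLAST-style
// convention used for the nucleotide scoring scheme (reward/penalty/gapopen/
// gapextend). Band W restricts cells to |j - i| <= W; the full matrix is the
// special case W >= max(n, m). Traceback state is packed one byte per cell.

static const double NEG_INF = -1e30;

// traceback codes for state M: 0 = from M, 1 = from X, 2 = from Y (diagonal)
// for state X (gap in b, consumes a): 0 = open from M, 1 = extend X, 2 = open from Y
// for state Y (gap in a, consumes b): 0 = open from M, 1 = extend Y, 2 = open from X

// [[Rcpp::export(name = ".band_align_cpp")]]
List band_align_cpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_ext,
                    int band) {
    const int n = (int) a.size();
    const int m = (int) b.size();
    if (n == 0 || m == 0) stop("empty sequence");
    int W = band;
    if (W < 0 || W > std::max(n, m)) W = std::max(n, m);
    if (std::abs(n - m) > W)
        stop("band infeasible: |len(a) - len(b)| exceeds the band width");

    const int bw = 2 * W + 1;             // cells per row
    const double oe = gap_open + gap_ext; // cost of opening a length-1 gap

    // rolling score rows; full traceback (packed: M src bits 0-1, X bits 2-3, Y bits 4-5)
    std::vector<double> Mprev(bw, NEG_INF), Xprev(bw, NEG_INF), Yprev(bw, NEG_INF);
    std::vector<double> Mcur(bw, NEG_INF), Xcur(bw, NEG_INF), Ycur(bw, NEG_INF);
    // guard against absurd allocations (~1 byte per cell)
    double cells = (double)(n + 1) * (double) bw;
    if (cells > 2.5e9)
        stop("alignment matrix too large; supply a band width");
    std::vector<uint8_t> tb((size_t)(n + 1) * (size_t) bw, 0);

    // row 0: j ranges over [0, min(m, W)]
    for (int j = 0; j <= std::min(m, W); ++j) {
        int k = j - 0 + W;
        if (j == 0) { Mprev[k] = 0.0; }
        else        { Yprev[k] = -(gap_open + gap_ext * j); tb[k] |= (1 << 4); }
    }

    for (int i = 1; i <= n; ++i) {
        std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
        std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
        std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
        const int jlo = std::max(0, i - W);
        const int jhi = std::min(m, i + W);
        const char ai = a[i - 1];
        uint8_t *tbrow = &tb[(size_t) i * (size_t) bw];
        for (int j = jlo; j <= jhi; ++j) {
            const int k = j - i + W;
            uint8_t code = 0;
            if (j == 0) {
                // leading gap in b
                Xcur[k] = -(gap_open + gap_ext * i);
                code |= (1 << 2); // extend X
                tbrow[k] = code;
                continue;
            }
            // M: diagonal from (i-1, j-1) -> same k in previous row
            {
                double dM = Mprev[k], dX = Xprev[k], dY = Yprev[k];
                double best = dM; uint8_t src = 0;
                if (dX > best) { best = dX; src = 1; }
                if (dY > best) { best = dY; src = 2; }
                if (best > NEG_INF / 2) {
                    double s = (ai == b[j - 1]) ? match : mismatch;
                    Mcur[k] = best + s;
                    code |= src;
                }
            }
            // X: vertical, consumes a_i, from (i-1, j) -> k+1 in previous row
            if (k + 1 < bw) {
                double fromM = (Mprev[k + 1] > NEG_INF / 2) ? Mprev[k + 1] - oe : NEG_INF;
                double fromX = (Xprev[k + 1] > NEG_INF / 2) ? Xprev[k + 1] - gap_ext : NEG_INF;
                double fromY = (Yprev[k + 1] > NEG_INF / 2) ? Yprev[k + 1] - oe : NEG_INF;
                double best = fromM; uint8_t src = 0;
                if (fromX > best) { best = fromX; src = 1; }
                if (fromY > best) { best = fromY; src = 2; }
                if (best > NEG_INF / 2) { Xcur[k] = best; code |= (src << 2); }
            }
            // Y: horizontal, consumes b_j, from (i, j-1) -> k-1 in current row
            if (k - 1 >= 0) {
                double fromM = (Mcur[k - 1] > NEG_INF / 2) ? Mcur[k - 1] - oe : NEG_INF;
                double fromY = (Ycur[k - 1] > NEG_INF / 2) ? Ycur[k - 1] - gap_ext : NEG_INF;
                double fromX = (Xcur[k - 1] > NEG_INF / 2) ? Xcur[k - 1] - oe : NEG_INF;
                double best = fromM; uint8_t src = 0;
                if (fromY > best) { best = fromY; src = 1; }
                if (fromX > best) { best = fromX; src = 2; }
                if (best > NEG_INF / 2) { Ycur[k] = best; code |= (src << 4); }
            }
            tbrow[k] = code;
        }
        std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    }

    const int kend = m - n + W;
    double sM = Mprev[kend], sX = Xprev[kend], sY = Yprev[kend];
    double score = sM; int state = 0; // 0 = M, 1 = X, 2 = Y
    if (sX > score) { score = sX; state = 1; }
    if (sY > score) { score = sY; state = 2; }
    if (score < NEG_INF / 2)
        stop("no alignment path inside the band");

    // traceback
    std::string out_a, out_b;
    out_a.reserve(n + m); out_b.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        const int k = j - i + W;
        const uint8_t code = tb[(size_t) i * (size_t) bw + k];
        if (state == 0) {
            // M consumed a_i and b_j
            out_a.push_back(a[i - 1]); out_b.push_back(b[j - 1]);
            state = code & 0x3;
            --i; --j;
        } else if (state == 1) {
            out_a.push_back(a[i - 1]); out_b.push_back('-');
            uint8_t src = (code >> 2) & 0x3;
            state = (src == 0) ? 0 : (src == 1 ? 1 : 2);
            --i;
        } else {
            out_a.push_back('-'); out_b.push_back(b[j - 1]);
            uint8_t src = (code >> 4) & 0x3;
            state = (src == 0) ? 0 : (src == 1 ? 2 : 1);
            --j;
        }
    }
    std::reverse(out_a.begin(), out_a.end());
    std::reverse(out_b.begin(), out_b.end());
    return List::create(_["aligned_a"] = out_a,
                        _["aligned_b"] = out_b,
                        _["score"] = score);
}
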