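// Core of the speckle-adapted block-matching 3D (S-BM3D) filter.
//
// Patch grouping uses the probabilistic amplitude distance for L-look
// square-root-Gamma speckle; groups are denoised collaboratively in an
// undecimated (tight-frame) Daubechies wavelet domain with an orthonormal
// Haar transform along the stacking axis, by LLMMSE shrinkage (pass 1) and
// empirical Wiener filtering against the pass-1 prior (pass 2); overlapping
// patch estimates are aggregated by an inverse-residual-variance weighted
// mean.  Everything is deterministic: no random state anywhere.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double AMP_EPS = 1e-6;   // amplitude clamp before log-ratio terms

// ---------------------------------------------------------------------------
// Wavelet machinery
// ---------------------------------------------------------------------------

// 8-tap Daubechies orthonormal lowpass (4 vanishing moments), sum = sqrt(2).
static const double DAUB8[8] = {
    -0.010597401784997278,  0.032883011666982945,
     0.030841381835986965, -0.187034811718881140,
    -0.027983769416983850,  0.630880767929590400,
     0.714846570552541500,  0.230377813308855230
};
static const int NTAP = 8;

struct WaveletBank {
    double hs[NTAP];  // analysis lowpass  / sqrt(2)  (tight frame scaling)
    double gs[NTAP];  // analysis highpass / sqrt(2)
    WaveletBank() {
        const double inv = 1.0 / std::sqrt(2.0);
        for (int n = 0; n < NTAP; ++n) {
            hs[n] = DAUB8[n] * inv;
            // quadrature mirror: g[n] = (-1)^n h[NTAP-1-n]
            gs[n] = ((n % 2) ? -1.0 : 1.0) * DAUB8[NTAP - 1 - n] * inv;
        }
    }
};
static const WaveletBank WB;

// circular correlation along a strided 1-D signal, dilation 2^(level-1)
static inline void conv1d(const double* x, int n, int stride,
                          const double* f, int dil, double* out) {
    for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int t = 0; t < NTAP; ++t) {
            int j = (i + t * dil) % n;
            s += f[t] * x[j * stride];
        }
        out[i] = s;
    }
}

// adjoint of conv1d (synthesis side of the tight frame)
static inline void conv1d_adj(const double* y, int n, const double* f,
                              int dil, double* acc, int stride) {
    for (int i = 0; i < n; ++i) {
        double v = y[i];
        for (int t = 0; t < NTAP; ++t) {
            int j = (i + t * dil) % n;
            acc[j * stride] += f[t] * v;
        }
    }
}

// Undecimated separable 2-D wavelet, `levels` scales, on a B x B patch
// (column-major, element (r,c) at r + c*B).  Subband order in `coef`:
// for l = 1..levels: LH(l), HL(l), HH(l); then LL(levels).
// Tight frame: inverse = adjoint; perfect reconstruction for any B.
struct Swt2 {
    int B, levels, nsub;
    std::vector<double> gains;  // white-noise variance gain per subband

    Swt2(int B_, int levels_) : B(B_), levels(levels_), nsub(3 * levels_ + 1) {
        compute_gains();
    }

    // forward: patch (B*B) -> coef (nsub*B*B)
    void forward(const double* patch, double* coef) const {
        int P = B * B;
        std::vector<double> a(patch, patch + P), Lr(P), Hr(P), nxt(P);
        std::vector<double> tmp(B);
        for (int l = 0; l < levels; ++l) {
            int dil = 1 << l;
            // along rows (vary column index, stride B)
            for (int r = 0; r < B; ++r) {
                conv1d(&a[r], B, B, WB.hs, dil, tmp.data());
                for (int c = 0; c < B; ++c) Lr[r + c * B] = tmp[c];
                conv1d(&a[r], B, B, WB.gs, dil, tmp.data());
                for (int c = 0; c < B; ++c) Hr[r + c * B] = tmp[c];
            }
            double* LH = coef + (3 * l + 0) * P;
            double* HL = coef + (3 * l + 1) * P;
            double* HH = coef + (3 * l + 2) * P;
            // along columns (stride 1)
            for (int c = 0; c < B; ++c) {
                conv1d(&Lr[c * B], B, 1, WB.hs, dil, &nxt[c * B]);   // LL
                conv1d(&Lr[c * B], B, 1, WB.gs, dil, &LH[c * B]);
                conv1d(&Hr[c * B], B, 1, WB.hs, dil, &HL[c * B]);
                conv1d(&Hr[c * B], B, 1, WB.gs, dil, &HH[c * B]);
            }
            a = nxt;
        }
        std::copy(a.begin(), a.end(), coef + 3 * levels * P);
    }

    // inverse (adjoint of the tight frame)
    void inverse(const double* coef, double* patch) const {
        int P = B * B;
        std::vector<double> a(coef + 3 * levels * P, coef + (3 * levels + 1) * P);
        std::vector<double> Lr(P), Hr(P), out(P);
        for (int l = levels - 1; l >= 0; --l) {
            int dil = 1 << l;
            const double* LH = coef + (3 * l + 0) * P;
            const double* HL = coef + (3 * l + 1) * P;
            const double* HH = coef + (3 * l + 2) * P;
            std::fill(Lr.begin(), Lr.end(), 0.0);
            std::fill(Hr.begin(), Hr.end(), 0.0);
            for (int c = 0; c < B; ++c) {
                conv1d_adj(&a[c * B],  B, WB.hs, dil, &Lr[c * B], 1);
                conv1d_adj(&LH[c * B], B, WB.gs, dil, &Lr[c * B], 1);
                conv1d_adj(&HL[c * B], B, WB.hs, dil, &Hr[c * B], 1);
                conv1d_adj(&HH[c * B], B, WB.gs, dil, &Hr[c * B], 1);
            }
            std::fill(out.begin(), out.end(), 0.0);
            std::vector<double> rowbuf(B);
            for (int r = 0; r < B; ++r) {
                for (int c = 0; c < B; ++c) rowbuf[c] = Lr[r + c * B];
                conv1d_adj(rowbuf.data(), B, WB.hs, 1 * dil, &out[r], B);
                for (int c = 0; c < B; ++c) rowbuf[c] = Hr[r + c * B];
                conv1d_adj(rowbuf.data(), B, WB.gs, 1 * dil, &out[r], B);
            }
            a = out;
        }
        std::copy(a.begin(), a.end(), patch);
    }

private:
    // exact white-noise variance gain of every subband: transform each of the
    // B*B unit impulses, accumulate squared coefficients, divide by B*B
    // (circular transforms are position-invariant so the average is exact).
    void compute_gains() {
        int P = B * B;
        gains.assign(nsub, 0.0);
        std::vector<double> imp(P), cf(nsub * P);
        for (int p = 0; p < P; ++p) {
            std::fill(imp.begin(), imp.end(), 0.0);
            imp[p] = 1.0;
            forward(imp.data(), cf.data());
            for (int s = 0; s < nsub; ++s)
                for (int q = 0; q < P; ++q)
                    gains[s] += cf[s * P + q] * cf[s * P + q];
        }
        for (int s = 0; s < nsub; ++s) gains[s] /= P;
    }
};

// orthonormal Haar along the stack axis, K a power of two (K <= 64)
static inline void haar_fwd(double* v, int K) {
    double tmp[64];
    const double s = std::sqrt(0.5);
    for (int len = K; len > 1; len >>= 1) {
        int h = len / 2;
        for (int i = 0; i < h; ++i) {
            tmp[i]     = (v[2 * i] + v[2 * i + 1]) * s;
            tmp[h + i] = (v[2 * i] - v[2 * i + 1]) * s;
        }
        std::copy(tmp, tmp + len, v);
    }
}
static inline void haar_inv(double* v, int K) {
    double tmp[64];
    const double s = std::sqrt(0.5);
    for (int len = 2; len <= K; len <<= 1) {
        int h = len / 2;
        for (int i = 0; i < h; ++i) {
            tmp[2 * i]     = (v[i] + v[h + i]) * s;
            tmp[2 * i + 1] = (v[i] - v[h + i]) * s;
        }
        std::copy(tmp, tmp + len, v);
    }
}

// ---------------------------------------------------------------------------
// Patch distance / block matching
// ---------------------------------------------------------------------------

// probabilistic distance between two patches located at (sr,sc), (tr,tc):
// sum over pixels of (2L-1) log(a_s/a_t + a_t/a_s) + gamma (p_s-p_t)^2/(p_s p_t)
static inline double patch_dist(const double* a, const double* prior,
                                int H, int sr, int sc, int tr, int tc,
                                int B, double c2l, double gamma,
                                double cutoff) {
    double d = 0.0;
    bool can_cut = (c2l >= 0.0 && gamma >= 0.0 && cutoff > 0.0);
    for (int c = 0; c < B; ++c) {
        const double* as = a + sr + (sc + c) * H;
        const double* at = a + tr + (tc + c) * H;
        for (int r = 0; r < B; ++r) {
            double ratio = as[r] / at[r];
            d += c2l * std::log(ratio + 1.0 / ratio);
            if (gamma > 0.0) {
                const double ps = std::max(prior[sr + r + (sc + c) * H], AMP_EPS);
                const double pt = std::max(prior[tr + r + (tc + c) * H], AMP_EPS);
                double diff = ps - pt;
                d += gamma * diff * diff / (ps * pt);
            }
        }
        if (can_cut && d >= cutoff) return d;
    }
    return d;
}

struct MatchSet {
    int maxg, cnt;
    std::vector<double> d;
    std::vector<int> r, c;
    MatchSet(int m) : maxg(m), cnt(0), d(m), r(m), c(m) {}
    double worst() const { return cnt == maxg ? d[cnt - 1] : R_PosInf; }
    void insert(double dd, int rr, int cc) {
        if (cnt == maxg && dd >= d[cnt - 1]) return;
        int pos = cnt < maxg ? cnt : cnt - 1;
        if (cnt < maxg) ++cnt;
        while (pos > 0 && d[pos - 1] > dd) {
            d[pos] = d[pos - 1]; r[pos] = r[pos - 1]; c[pos] = c[pos - 1];
            --pos;
        }
        d[pos] = dd; r[pos] = rr; c[pos] = cc;
    }
};

// exhaustive scan of the search window; reference always retained (it is
// inserted first and attains the minimal possible distance, so ties cannot
// displace it).
static void block_match_core(const double* a, const double* prior,
                             int H, int W, int refR, int refC,
                             int B, int S, double c2l, double gamma,
                             MatchSet& ms) {
    ms.cnt = 0;
    // self distance through the same accumulation as every candidate, so a
    // tying candidate can never displace the reference by a rounding ulp
    ms.insert(patch_dist(a, prior, H, refR, refC, refR, refC, B,
                         c2l, gamma, R_PosInf),
              refR, refC);
    int half = (S - B) / 2;
    int r0 = std::max(0, refR - half), r1 = std::min(H - B, refR + half);
    int c0 = std::max(0, refC - half), c1 = std::min(W - B, refC + half);
    for (int cc = c0; cc <= c1; ++cc) {
        for (int rr = r0; rr <= r1; ++rr) {
            if (rr == refR && cc == refC) continue;
            double dd = patch_dist(a, prior, H, refR, refC, rr, cc, B,
                                   c2l, gamma, ms.worst());
            ms.insert(dd, rr, cc);
        }
    }
}

// ---------------------------------------------------------------------------
// Group shrinkage
// ---------------------------------------------------------------------------

// forward transform of a K-patch stack: 2-D SWT per patch then Haar across
// the stack for every coefficient index.  coef layout: ((k*nsub+s)*B+r)*B+c
static void group_forward(const Swt2& wt, const double* stack, int K,
                          double* coef) {
    int P = wt.B * wt.B, CP = wt.nsub * P;
    for (int k = 0; k < K; ++k)
        wt.forward(stack + k * P, coef + k * CP);
    double buf[64];
    for (int q = 0; q < CP; ++q) {
        for (int k = 0; k < K; ++k) buf[k] = coef[k * CP + q];
        haar_fwd(buf, K);
        for (int k = 0; k < K; ++k) coef[k * CP + q] = buf[k];
    }
}

static void group_inverse(const Swt2& wt, double* coef, int K, double* stack) {
    int P = wt.B * wt.B, CP = wt.nsub * P;
    double buf[64];
    for (int q = 0; q < CP; ++q) {
        for (int k = 0; k < K; ++k) buf[k] = coef[k * CP + q];
        haar_inv(buf, K);
        for (int k = 0; k < K; ++k) coef[k * CP + q] = buf[k];
    }
    for (int k = 0; k < K; ++k)
        wt.inverse(coef + k * CP, stack + k * P);
}

// LLMMSE shrinkage: per (subband, stack-slice), mean mu and total variance
// from the slice's coefficients; sigma_n^2 = subband gain * pixel noise
// variance (Haar across the stack is orthonormal, leaving it unchanged);
// x^ = mu + sx2/(sx2+sn2) (y - mu), sx2 = max(0, total - sn2).
static void stage1_shrink(const Swt2& wt, double* coef, int K,
                          double sigmaPix2) {
    int P = wt.B * wt.B, CP = wt.nsub * P;
    for (int k = 0; k < K; ++k) {
        for (int s = 0; s < wt.nsub; ++s) {
            double* y = coef + k * CP + s * P;
            double sn2 = wt.gains[s] * sigmaPix2;
            if (sn2 <= 0.0) continue;                  // shrinkage factor 1
            double mu = 0.0;
            for (int q = 0; q < P; ++q) mu += y[q];
            mu /= P;
            double tot = 0.0;
            for (int q = 0; q < P; ++q) tot += (y[q] - mu) * (y[q] - mu);
            tot /= P;
            double sx2 = std::max(0.0, tot - sn2);
            double fac = sx2 / (sx2 + sn2);
            for (int q = 0; q < P; ++q) y[q] = mu + fac * (y[q] - mu);
        }
    }
}

// empirical Wiener: X^ = P^2/(P^2 + <V^2>) Z with <V^2> the mean squared
// prior-noisy coefficient difference over the (subband, slice) support.
static void stage2_shrink(const Swt2& wt, const double* prior, double* noisy,
                          int K) {
    int P = wt.B * wt.B, CP = wt.nsub * P;
    for (int k = 0; k < K; ++k) {
        for (int s = 0; s < wt.nsub; ++s) {
            const double* pc = prior + k * CP + s * P;
            double* zc = noisy + k * CP + s * P;
            double v2 = 0.0;
            for (int q = 0; q < P; ++q) {
                double dv = pc[q] - zc[q];
                v2 += dv * dv;
            }
            v2 /= P;
            for (int q = 0; q < P; ++q) {
                double num = pc[q] * pc[q];
                double den = num + v2;
                zc[q] = (den > 0.0) ? num / den * zc[q] : 0.0;
            }
        }
    }
}

static inline int pow2_floor(int n) {
    int k = 1;
    while (2 * k <= n) k *= 2;
    return k;
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_patch_distance(NumericMatrix as, NumericMatrix at,
                          Nullable<NumericMatrix> ps, Nullable<NumericMatrix> pt,
                          double looks, double gamma) {
    int n = as.size();
    double c2l = 2.0 * looks - 1.0, d = 0.0;
    NumericMatrix psm, ptm;
    if (gamma > 0.0) { psm = NumericMatrix(ps); ptm = NumericMatrix(pt); }
    for (int i = 0; i < n; ++i) {
        double x = std::max(as[i], AMP_EPS), y = std::max(at[i], AMP_EPS);
        double ratio = x / y;
        d += c2l * std::log(ratio + 1.0 / ratio);
        if (gamma > 0.0) {
            double a = std::max(psm[i], AMP_EPS), b = std::max(ptm[i], AMP_EPS);
            double diff = a - b;
            d += gamma * diff * diff / (a * b);
        }
    }
    return d;
}

// [[Rcpp::export]]
List cpp_block_match(NumericMatrix img, Nullable<NumericMatrix> prior,
                     int refR, int refC, int block, int search,
                     int maxGroup, double looks, double gamma) {
    int H = img.nrow(), W = img.ncol();
    std::vector<double> a(img.begin(), img.end());
    for (double& v : a) v = std::max(v, AMP_EPS);
    std::vector<double> pr;
    const double* prp = NULL;
    if (gamma > 0.0) {
        NumericMatrix pm(prior);
        pr.assign(pm.begin(), pm.end());
        prp = pr.data();
    }
    MatchSet ms(maxGroup);
    block_match_core(a.data(), prp, H, W, refR, refC, block, search,
                     2.0 * looks - 1.0, gamma, ms);
    return List::create(_["rows"] = IntegerVector(ms.r.begin(), ms.r.begin() + ms.cnt),
                        _["cols"] = IntegerVector(ms.c.begin(), ms.c.begin() + ms.cnt),
                        _["dist"] = NumericVector(ms.d.begin(), ms.d.begin() + ms.cnt));
}

// [[Rcpp::export]]
List cpp_swt2_forward(NumericVector stack, int K, int B, int levels) {
    Swt2 wt(B, levels);
    int P = B * B, CP = wt.nsub * P;
    NumericVector coef(K * CP);
    for (int k = 0; k < K; ++k)
        wt.forward(&stack[k * P], &coef[k * CP]);
    return List::create(_["coef"] = coef,
                        _["nsub"] = wt.nsub,
                        _["gains"] = NumericVector(wt.gains.begin(), wt.gains.end()));
}

// [[Rcpp::export]]
NumericVector cpp_swt2_inverse(NumericVector coef, int K, int B, int levels) {
    Swt2 wt(B, levels);
    int P = B * B, CP = wt.nsub * P;
    NumericVector stack(K * P);
    for (int k = 0; k < K; ++k)
        wt.inverse(&coef[k * CP], &stack[k * P]);
    return stack;
}

// [[Rcpp::export]]
NumericVector cpp_stage1(NumericVector stack, int K, int B, int levels,
                         double sigmaPix2) {
    if ((K & (K - 1)) != 0)
        stop("stack depth must be a power of two");
    Swt2 wt(B, levels);
    int P = B * B, CP = wt.nsub * P;
    std::vector<double> coef(K * CP);
    group_forward(wt, &stack[0], K, coef.data());
    stage1_shrink(wt, coef.data(), K, sigmaPix2);
    NumericVector out(K * P);
    group_inverse(wt, coef.data(), K, &out[0]);
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_stage2(NumericVector noisy, NumericVector prior,
                         int K, int B, int levels) {
    if ((K & (K - 1)) != 0)
        stop("stack depth must be a power of two");
    Swt2 wt(B, levels);
    int P = B * B, CP = wt.nsub * P;
    std::vector<double> zc(K * CP), pc(K * CP);
    group_forward(wt, &noisy[0], K, zc.data());
    group_forward(wt, &prior[0], K, pc.data());
    stage2_shrink(wt, pc.data(), zc.data(), K);
    NumericVector out(K * P);
    group_inverse(wt, zc.data(), K, &out[0]);
    return out;
}

// one full denoising pass over the (already padded) image
static void sbm3d_pass(const double* img, const double* a, const double* prior,
                       int H, int W, int B, int S, int step, int maxG,
                       double c2l, double gamma, double sigmaU2,
                       const Swt2& wt, bool wiener,
                       std::vector<double>& num, std::vector<double>& wsum) {
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(wsum.begin(), wsum.end(), 0.0);
    int P = B * B, CP = wt.nsub * P;

    std::vector<int> rs, cs;
    for (int r = 0; r + B <= H; r += step) rs.push_back(r);
    if (rs.back() != H - B) rs.push_back(H - B);
    for (int c = 0; c + B <= W; c += step) cs.push_back(c);
    if (cs.back() != W - B) cs.push_back(W - B);

    MatchSet ms(maxG);
    std::vector<double> stack(maxG * P), pstack(maxG * P);
    std::vector<double> coef(maxG * CP), pcoef(maxG * CP), den(maxG * P);

    for (size_t ri = 0; ri < rs.size(); ++ri) {
        for (size_t ci = 0; ci < cs.size(); ++ci) {
            int refR = rs[ri], refC = cs[ci];
            block_match_core(a, prior, H, W, refR, refC, B, S, c2l, gamma, ms);
            int K = pow2_floor(ms.cnt);
            // gather stacks
            for (int k = 0; k < K; ++k)
                for (int c = 0; c < B; ++c)
                    for (int r = 0; r < B; ++r)
                        stack[k * P + r + c * B] =
                            img[ms.r[k] + r + (ms.c[k] + c) * H];
            if (wiener) {
                for (int k = 0; k < K; ++k)
                    for (int c = 0; c < B; ++c)
                        for (int r = 0; r < B; ++r)
                            pstack[k * P + r + c * B] =
                                prior[ms.r[k] + r + (ms.c[k] + c) * H];
                group_forward(wt, stack.data(), K, coef.data());
                group_forward(wt, pstack.data(), K, pcoef.data());
                stage2_shrink(wt, pcoef.data(), coef.data(), K);
            } else {
                double mbar = 0.0;
                for (int q = 0; q < K * P; ++q) mbar += stack[q];
                mbar /= K * P;
                group_forward(wt, stack.data(), K, coef.data());
                stage1_shrink(wt, coef.data(), K, sigmaU2 * mbar * mbar);
            }
            group_inverse(wt, coef.data(), K, den.data());
            // inverse-residual-variance aggregation weight
            double res = 0.0;
            for (int q = 0; q < K * P; ++q) {
                double dv = den[q] - stack[q];
                res += dv * dv;
            }
            res /= K * P;
            double w = 1.0 / (1.0 + res);
            for (int k = 0; k < K; ++k)
                for (int c = 0; c < B; ++c)
                    for (int r = 0; r < B; ++r) {
                        int px = ms.r[k] + r + (ms.c[k] + c) * H;
                        num[px]  += w * den[k * P + r + c * B];
                        wsum[px] += w;
                    }
        }
    }
}

// Full two-pass S-BM3D on an image already padded by the caller.
// sigmaU2 is the variance of the unit-mean amplitude speckle multiplier.
// [[Rcpp::export]]
NumericMatrix cpp_sbm3d(NumericMatrix img, int block, int search, int step,
                        int maxGroup, double looks, double gamma, int levels,
                        double sigmaU2, bool twoStage) {
    int H = img.nrow(), W = img.ncol();
    if (H < block || W < block) stop("image smaller than one block");
    if (maxGroup > 64) stop("max_group capped at 64");
    double c2l = 2.0 * looks - 1.0;
    Swt2 wt(block, levels);

    std::vector<double> x(img.begin(), img.end());
    std::vector<double> a(x);
    for (double& v : a) v = std::max(v, AMP_EPS);

    std::vector<double> num(H * W), wsum(H * W), prior(H * W);
    sbm3d_pass(x.data(), a.data(), NULL, H, W, block, search, step, maxGroup,
               c2l, 0.0, sigmaU2, wt, false, num, wsum);
    for (int i = 0; i < H * W; ++i) {
        if (!(wsum[i] > 0.0))
            stop("pixel (%d,%d) left uncovered by every group (wsum=%g)",
                 i % H, i / H, wsum[i]);
        prior[i] = num[i] / wsum[i];
    }
    NumericMatrix out(H, W);
    if (!twoStage) {
        std::copy(prior.begin(), prior.end(), out.begin());
        return out;
    }
    sbm3d_pass(x.data(), a.data(), prior.data(), H, W, block, search, step,
               maxGroup, c2l, gamma, sigmaU2, wt, true, num, wsum);
    for (int i = 0; i < H * W; ++i) {
        if (!(wsum[i] > 0.0))
            stop("pixel (%d,%d) left uncovered by every group (wsum=%g)",
                 i % H, i / H, wsum[i]);
        out[i] = num[i] / wsum[i];
    }
    return out;
}
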