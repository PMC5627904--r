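#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Affine-gap semi-global alignment (Gotoh): the query is aligned end-to-end,
// end gaps on the reference are free.  Gap of length L costs
// gap_open + (L - 1) * gap_extend.  'N' scores as a mismatch against
// everything, including itself.
//
// Traceback is deterministic: indels are placed as late (3'-ward) on the
// query as possible.  Entering a match/mismatch column the predecessor state
// priority is I > D > M; within gap states the gap is closed (M) before being
// extended; the final column prefers M over I and the smallest reference end.

static inline double subscore(char a, char b, double match, double mismatch) {
    return (a == b && a != 'N') ? match : mismatch;
}

#define S_M 0
#define S_I 1
#define S_D 2
#define S_START 3

// [[Rcpp::export(name = ".semiglobal_cpp")]]
List semiglobal_cpp(std::string q, std::string r,
                    double match, double mismatch,
                    double gap_open, double gap_ext) {
    const int m = (int) q.size(), n = (int) r.size();
    if (m < 1 || n < 1) stop("empty sequence");
    const double NEG = -1e30;
    const size_t W = (size_t) n + 1;
    std::vector<double> M((size_t)(m + 1) * W, NEG);
    std::vector<double> I((size_t)(m + 1) * W, NEG);
    std::vector<double> D((size_t)(m + 1) * W, NEG);
    std::vector<uint8_t> pM((size_t)(m + 1) * W, S_START);
    std::vector<uint8_t> pI((size_t)(m + 1) * W, S_START);
    std::vector<uint8_t> pD((size_t)(m + 1) * W, S_START);

    for (int j = 0; j <= n; ++j) M[j] = 0.0;  // free leading reference gap

    for (int i = 1; i <= m; ++i) {
        const size_t row = (size_t) i * W, prow = row - W;
        for (int j = 0; j <= n; ++j) {
            // I: consume a query base against a gap
            {
                double vM = M[prow + j] + gap_open;
                double vI = I[prow + j] + gap_ext;
                double vD = D[prow + j] + gap_open;
                double best = vM; uint8_t pb = S_M;
                if (vI > best) { best = vI; pb = S_I; }
                if (vD > best) { best = vD; pb = S_D; }
                I[row + j] = best; pI[row + j] = pb;
            }
            if (j > 0) {
                // M: diagonal; predecessor priority I > D > M
                double s = subscore(q[i - 1], r[j - 1], match, mismatch);
                double vI = I[prow + j - 1], vD = D[prow + j - 1], vM = M[prow + j - 1];
                double best = vI; uint8_t pb = S_I;
                if (vD > best) { best = vD; pb = S_D; }
                if (vM > best) { best = vM; pb = S_M; }
                M[row + j] = best + s; pM[row + j] = pb;
                // D: consume a reference base against a gap
                double dM = M[row + j - 1] + gap_open;
                double dI = I[row + j - 1] + gap_open;
                double dD = D[row + j - 1] + gap_ext;
                double bd = dM; uint8_t pd = S_M;
                if (dI > bd) { bd = dI; pd = S_I; }
                if (dD > bd) { bd = dD; pd = S_D; }
                D[row + j] = bd; pD[row + j] = pd;
            }
        }
    }

    // free trailing reference gap: best over final row, M preferred, smallest j
    double bestScore = NEG; int bj = 0; uint8_t bstate = S_M;
    const size_t lrow = (size_t) m * W;
    for (int j = 0; j <= n; ++j) {
        if (M[lrow + j] > bestScore) { bestScore = M[lrow + j]; bj = j; bstate = S_M; }
        if (I[lrow + j] > bestScore) { bestScore = I[lrow + j]; bj = j; bstate = S_I; }
    }

    std::string ops; ops.reserve((size_t) m + n);
    int i = m, j = bj; uint8_t st = bstate;
    while (i > 0) {
        const size_t row = (size_t) i * W;
        if (st == S_M) {
            ops.push_back((q[i - 1] == r[j - 1] && q[i - 1] != 'N') ? '=' : 'X');
            st = pM[row + j]; --i; --j;
        } else if (st == S_I) {
            ops.push_back('I');
            st = pI[row + j]; --i;
        } else {
            ops.push_back('D');
            st = pD[row + j]; --j;
        }
    }
    std::reverse(ops.begin(), ops.end());

    return List::create(_["score"] = bestScore,
                        _["ops"] = ops,
                        _["ref_start"] = j,
                        _["ref_end"] = bj);
}
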