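#!/usr/bin/env python
"""Exact right-tail hypergeometric probabilities by big-integer arithmetic.

For every valid tuple (k, K, n, N) with 1 <= N <= Nmax, prints
P[X >= k] for X ~ Hypergeometric(N, K, n) as a correctly rounded double
(big-integer numerator / denominator), one value per line, in the fixed
nesting order: N = 1..Nmax; n = 0..N; K = 0..N; k = 0..min(K, n).
Exactness: all intermediate arithmetic is integer; the only rounding is
the final division, which Python performs correctly rounded.

Usage: python hypergeom_exact.py Nmax > values.txt
"""
import sys


def main(nmax):
    # Pascal's triangle of exact binomials
    C = [[0] * (nmax + 1) for _ in range(nmax + 1)]
    for i in range(nmax + 1):
        C[i][0] = 1
        for j in range(1, i + 1):
            C[i][j] = C[i - 1][j - 1] + C[i - 1][j]
    out = []
    for N in range(1, nmax + 1):
        for n in range(N + 1):
            for K in range(N + 1):
                m = min(K, n)
                terms = [C[K][i] * C[N - K][n - i] for i in range(m + 1)]
                den = C[N][n]
                # suffix sums: tail[k] = sum_{i>=k} terms[i]
                tail = 0
                tails = [0] * (m + 1)
                for i in range(m, -1, -1):
                    tail += terms[i]
                    tails[i] = tail
                for k in range(m + 1):
                    out.append(repr(tails[k] / den))
        sys.stdout.write("\n".join(out) + "\n")
        out = []


if __name__ == "__main__":
    main(int(sys.argv[1]) if len(sys.argv) > 1 else 60)
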