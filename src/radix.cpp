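#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Arbitrary-precision radix conversion for payload-sized bit strings.
// Numbers are held as little-endian vectors of 32-bit limbs; divmod and
// multiply-accumulate by a small radix are O(limbs) per digit, so a
// 16385-bit payload converts to base 9 in a few million word operations.

// [[Rcpp::export(name = ".cpp_bits_to_digits")]]
IntegerVector cpp_bits_to_digits(const IntegerVector& bits, int radix) {
    if (radix < 2)
        stop("radix must be >= 2");
    const R_xlen_t n = bits.size();
    // pack bits (most significant first) into little-endian 32-bit limbs
    std::vector<uint32_t> limbs((n + 31) / 32, 0u);
    for (R_xlen_t i = 0; i < n; ++i) {
        int b = bits[n - 1 - i];           // bit i counted from the LSB
        if (b != 0 && b != 1)
            stop("bits must contain only 0 and 1");
        if (b)
            limbs[i / 32] |= (1u << (i % 32));
    }
    // strip leading zero limbs
    size_t top = limbs.size();
    while (top > 0 && limbs[top - 1] == 0u) --top;
    limbs.resize(top);

    std::vector<int> digits;
    if (limbs.empty()) {
        digits.push_back(0);
    } else {
        const uint64_t B = (uint64_t)radix;
        while (!limbs.empty()) {
            uint64_t rem = 0;
            for (size_t i = limbs.size(); i-- > 0; ) {
                uint64_t cur = (rem << 32) | limbs[i];
                limbs[i] = (uint32_t)(cur / B);
                rem = cur % B;
            }
            digits.push_back((int)rem);
            while (!limbs.empty() && limbs.back() == 0u)
                limbs.pop_back();
        }
    }
    IntegerVector out(digits.size());
    for (size_t i = 0; i < digits.size(); ++i)      // most significant first
        out[i] = digits[digits.size() - 1 - i];
    return out;
}

// [[Rcpp::export(name = ".cpp_digits_to_bits")]]
IntegerVector cpp_digits_to_bits(const IntegerVector& digits, int radix) {
    if (radix < 2)
        stop("radix must be >= 2");
    std::vector<uint32_t> limbs;
    const uint64_t B = (uint64_t)radix;
    for (R_xlen_t k = 0; k < digits.size(); ++k) {
        int d = digits[k];
        if (d < 0 || d >= radix)
            stop("digit out of range for radix");
        uint64_t carry = (uint64_t)d;                // limbs = limbs*B + d
        for (size_t i = 0; i < limbs.size(); ++i) {
            uint64_t cur = (uint64_t)limbs[i] * B + carry;
            limbs[i] = (uint32_t)(cur & 0xffffffffu);
            carry = cur >> 32;
        }
        while (carry) {
            limbs.push_back((uint32_t)(carry & 0xffffffffu));
            carry >>= 32;
        }
    }
    while (!limbs.empty() && limbs.back() == 0u)
        limbs.pop_back();
    if (limbs.empty())
        return IntegerVector::create(0);             // the value zero is "0"
    // locate the highest set bit
    uint32_t hi = limbs.back();
    int hibit = 31;
    while (!(hi & (1u << hibit))) --hibit;
    R_xlen_t nbits = (R_xlen_t)(limbs.size() - 1) * 32 + hibit + 1;
    IntegerVector out(nbits);
    for (R_xlen_t i = 0; i < nbits; ++i) {
        R_xlen_t pos = nbits - 1 - i;                // bit pos from LSB
        out[i] = (limbs[pos / 32] >> (pos % 32)) & 1u;
    }
    return out;
}
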