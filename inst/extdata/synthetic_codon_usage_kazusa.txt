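# synthetic codon usage table (Kazusa-style layout); frequencies are
# constructed for examples and tests, not measured from any genome
AAA 28.1( 23126)  AAC 22.5( 18518)  AAG  6.0(  4938)  AAU 11.8(  9711)
ACA 22.4( 18435)  ACC  1.5(  1234)  ACG 18.9( 15555)  ACU 34.5( 28394)
AGA 10.5(  8642)  AGC 23.4( 19258)  AGG  0.7(   576)  AGU 27.8( 22879)
AUA  9.6(  7901)  AUC 34.0( 27982)  AUG  6.6(  5432)  AUU 14.6( 12016)
CAA 22.0( 18106)  CAC  0.5(   412)  CAG 13.1( 10781)  CAU  1.2(   988)
CCA 14.0( 11522)  CCC 14.1( 11604)  CCG  9.7(  7983)  CCU  2.9(  2387)
CGA 16.8( 13826)  CGC  7.8(  6419)  CGG 16.7( 13744)  CGU  6.0(  4938)
CUA  0.7(   576)  CUC 24.3( 19999)  CUG 36.5( 30040)  CUU  7.4(  6090)
GAA 29.4( 24196)  GAC  1.1(   905)  GAG 23.7( 19505)  GAU 17.3( 14238)
GCA  8.8(  7242)  GCC 19.3( 15884)  GCG 30.3( 24937)  GCU 18.1( 14896)
GGA 15.2( 12510)  GGC 35.1( 28887)  GGG 17.7( 14567)  GGU 17.9( 14732)
GUA  3.7(  3045)  GUC  1.9(  1564)  GUG 37.2( 30616)  GUU 12.1(  9958)
UAA 21.0( 17283)  UAC  9.8(  8065)  UAG 38.9( 32015)  UAU 25.5( 20986)
UCA 38.4( 31603)  UCC 35.5( 29216)  UCG 21.2( 17448)  UCU 28.8( 23702)
UGA 29.8( 24525)  UGC  2.3(  1893)  UGG 38.3( 31521)  UGU  8.4(  6913)
UUA 12.3( 10123)  UUC 35.9( 29546)  UUG 22.9( 18847)  UUU 18.5( 15226)
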