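# Synthetic stand-in for the full-EC key set of the PM reference side,
# restricted to the functions needed to label the two transcribed
# B. subtilis neighborhood fixtures: it contains exactly the complete EC
# numbers of the genes that carry a "P" in the published tables.
3.1.3.16
2.7.11.1
6.3.4.19
2.4.2.8
2.7.1.33
2.5.1.47
2.6.1.85
4.1.3.38
2.5.1.15
4.1.2.25
2.7.6.3
6.1.1.6
2.5.1.19
1.3.1.12
2.6.1.9
4.2.1.20
5.3.1.24
4.1.1.48
2.4.2.18
4.1.3.27
5.4.99.5
4.2.3.4
4.2.3.5
2.1.1.80
2.7.4.6
2.5.1.30
3.5.4.16
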