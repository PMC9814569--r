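>CATCH_like(2+) acetylated=true amidated=true
QQQFKWKFQQQ
>CATCH_like(2-) acetylated=true amidated=true
QQQFEWEFQQQ
>CATCH_like(4+) acetylated=true amidated=true
QQKFKWKFKQQ
>CATCH_like(4-) acetylated=true amidated=true
QQEFEWEFEQQ
>CATCH_like(6+) acetylated=true amidated=true
KQKFKWKFKQK
>CATCH_like(6-) acetylated=true amidated=true
EQEFEWEFEQE
>Q11 acetylated=true amidated=true
QQKFQFQFEQQ
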