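>RSAH k=3
A	0.1	0.38	0.36
C	0.04	0.38	0.52
G	0.42	0.24	0.04
T	0.44	0	0.08
>SAEH k=3
A	0.12	0.02	0.42
C	0	0.56	0
G	0.34	0.26	0.48
T	0.54	0.16	0.1
>RKHK k=3
A	0.236709	0.395738	0.129191
C	0.0388906	0.103257	0.0574593
G	0.171607	0.437015	0.404251
T	0.552794	0.0639893	0.409099
>AKKR k=3
A	0.135551	0.117006	0.401515
C	0.260513	0.0121491	0.558494
G	0.120533	0.356407	0.0175866
T	0.483402	0.514437	0.0224044
>NRAH k=3
A	0.08	0.5	0.82
C	0.02	0.32	0.08
G	0.32	0.18	0.08
T	0.58	0	0.02
>ANNN k=3
A	0.86	0.04	0.02
C	0.1	0.08	0.86
G	0.04	0.8	0.08
T	0	0.08	0.04
>SNDH k=3
A	0.04	0.14	0
C	0	0.2	0.86
G	0.34	0.34	0.12
T	0.62	0.32	0.02
>HKSA k=3
A	0	0.34	0.22
C	0.12	0.32	0
G	0.88	0.08	0.34
T	0	0.26	0.44
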