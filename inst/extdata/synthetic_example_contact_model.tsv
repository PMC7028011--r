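# contact_threshold=0.10000000000000001
dbd_position	1	2	3
1	0.0092441129963845015	0.0064579488360323014	0.038025665655732156
2	0.035118701797910039	0.041672440781258049	0.27750990851782265
3	0.028666316741146149	0.023400925775058569	0.90971392550971364
4	0.008402596018277109	0.87449876548256733	0.042677422647830102
5	0.89668855374678968	0.027633703348692508	0.048819924471899867
6	0.047173747932538396	0.011944737972225995	0.011291273054666817
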