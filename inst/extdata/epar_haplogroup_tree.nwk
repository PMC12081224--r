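(((E1a-M132,E1b-M215)E1,((((I1a-Z58,I1a-Z63)I1a,(I1c-Z17954,I1c-Z2541)I1c)I1,((I2a-M223,I2a-M284)I2a2,((I2a-L233,I2a-L1286)I2a1b,(I2a-L1294,I2a-M26)I2a1a)I2a1)I2a)I,(J2-M172,G2a-P15)JG)IJG)W1,((K-M9,NO-M214)K2b,((R1a-M417,Q-M242)QR,(R1b-U106,(R1b-L52,((R1b-U152,R1b-DF27)U152p,(R1b-CTS3655,R1b-Z290)C3655p)P312)L51)R1b)PQR)K2)Root;
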