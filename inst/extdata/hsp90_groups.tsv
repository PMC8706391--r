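group	id
1	M61
1	M08
1	M17
1	M24
1	M60
2	M35
2	M36
2	M69
2	M70
2	M17
2	M24
2	M60
2	M05
2	M18
2	M19
3	M01
3	M02
3	M03
3	M37
3	M38
3	M39
3	M17
3	M24
3	M60
3	M05
3	M18
3	M19
3	M20
3	M21
3	M59
4	M31
4	M32
4	M33
4	M34
4	M65
4	M66
4	M67
4	M68
4	M17
4	M24
4	M60
4	M05
4	M18
4	M19
4	M20
4	M21
4	M22
4	M51
4	M58
4	M59
5	M04
5	M06
5	M07
5	M09
5	M10
5	M40
5	M41
5	M42
5	M43
5	M44
5	M17
5	M24
5	M60
5	M05
5	M18
5	M19
5	M20
5	M21
5	M22
5	M23
5	M51
5	M52
5	M53
5	M58
5	M59
6	M25
6	M26
6	M27
6	M28
6	M29
6	M30
6	M48
6	M49
6	M50
6	M62
6	M63
6	M64
6	M17
6	M24
6	M60
6	M05
6	M18
6	M19
6	M20
6	M21
6	M22
6	M23
6	M51
6	M52
6	M53
6	M71
6	M54
6	M55
6	M58
6	M59
7	M11
7	M12
7	M13
7	M14
7	M15
7	M25
7	M26
7	M27
7	M45
7	M46
7	M47
7	M48
7	M49
7	M50
7	M62
7	M63
7	M17
7	M24
7	M60
7	M05
7	M18
7	M19
7	M20
7	M21
7	M22
7	M23
7	M51
7	M52
7	M53
7	M71
7	M54
7	M55
7	M56
7	M58
7	M59
8	M61
8	M01
8	M02
8	M03
8	M04
8	M06
8	M07
8	M09
8	M10
8	M11
8	M27
8	M28
8	M29
8	M30
8	M31
8	M32
8	M33
8	M34
8	M35
8	M36
8	M08
8	M37
8	M38
8	M39
8	M40
8	M41
8	M42
8	M43
8	M44
8	M45
8	M50
8	M62
8	M63
8	M64
8	M65
8	M66
8	M67
8	M68
8	M69
8	M70
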