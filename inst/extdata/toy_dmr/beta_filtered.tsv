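chrom	pos	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10	S11	S12
chr1	1000	0.8634	0.7913	0.8067	0.7773	0.7355	0.7401	0.8669	0.8494	0.8249	0.8809	0.7284	0.8632
chr1	1100	0.7612	0.8262	0.8634	0.7683	0.7154	0.7401	0.8675	0.7357	0.7075	0.8135	0.8571	0.7822
chr1	1210	0.8547	0.8395	0.7069	0.787	0.7967	0.7184	0.794	0.8914	0.8664	0.882	0.8096	0.808
chr1	1690	0.8795	0.7464	0.7795	0.818	0.8958	0.7458	0.7307	0.7535	0.7522	0.7656	0.8645	0.8962
chr1	1900	0.828	0.8723	0.806	0.7036	0.7737	0.7582	0.8878	0.832	0.7777	0.8969	0.8095	0.8863
chr1	2520	0.7582	0.815	0.7564	0.873	0.7526	0.8124	0.8966	0.8387	0.7937	0.8926	0.7777	0.8782
chr1	3530	0.8199	0.826	0.782	0.8742	0.7194	0.8594	0.8633	0.8577	0.7052	0.8735	0.7226	0.8485
chr1	3910	0.7068	0.7266	0.7264	0.7709	0.7889	0.8738	0.7939	0.8474	0.7062	0.8961	0.7009	0.8142
chr1	4410	0.8436	0.8936	0.8181	0.8814	0.8985	0.786	0.7827	0.7067	0.8542	0.7716	0.7391	0.7704
chr1	5000	0.8283	0.8082	0.7839	0.8417	0.8301	0.7246	0.8289	0.8921	0.0675	0.0596	0.0717	0.0565
chr1	5060	0.8324	0.7262	0.7328	0.8107	0.7897	0.8463	0.8	0.8149	0.0943	0.0665	0.142	0.1341
chr1	5120	0.7079	0.8239	0.7209	0.8131	0.7104	0.8606	0.8113	0.7772	0.0552	0.1272	0.135	0.1073
chr1	5200	0.7509	0.8199	0.7667	0.8439	0.8537	0.8774	0.791	0.7496	0.0712	0.1387	0.0885	0.0579
chr1	5280	0.8766	0.7118	0.7966	0.8161	0.8793	0.8652	0.7682	0.7363	0.0828	0.132	0.0836	0.0539
chr1	5340	0.8994	0.7508	0.8635	0.7595	0.7616	0.8628	0.8421	0.7538	0.1283	0.1496	0.1341	0.1381
chr1	6400	0.8163	0.7365	0.8844	0.7011	0.7061	0.7882	0.8007	0.7085	0.833	0.8772	0.8438	0.746
chr1	6440	0.8923	0.737	0.8188	0.7325	0.7376	0.7218	0.7562	0.774	0.8347	0.8078	0.7714	0.733
chr1	6590	0.8693	0.8661	0.7322	0.8249	0.8683	0.8797	0.7793	0.8121	0.8115	0.8186	0.8204	0.8967
chr1	7780	0.8655	0.8774	0.7493	0.8452	0.7019	0.7595	0.8651	0.8346	0.8892	0.819	0.727	0.8813
chr1	8190	0.735	0.7923	0.8538	0.75	0.7884	0.7576	0.7656	0.7222	0.8641	0.7802	0.8768	0.7656
chr1	8300	0.7432	0.8016	0.8023	0.8905	0.7627	0.7532	0.855	0.717	0.7517	0.8592	0.8394	0.8586
chr1	9390	0.7356	0.8953	0.8496	0.7498	0.8363	0.7165	0.8758	0.7299	0.8706	0.7022	0.801	0.8383
chr1	10030	0.7158	0.8974	0.7928	0.7316	0.8798	0.7814	0.8953	0.7359	0.7753	0.7397	0.815	0.8612
chr1	10060	0.8753	0.757	0.825	0.7103	0.7535	0.8766	0.7617	0.8454	0.8703	0.8304	0.816	0.7297
chr1	10110	0.772	0.8389	0.7921	0.8167	0.8872	0.8273	0.8023	0.8791	0.8388	0.8468	0.8841	0.871
chr1	10830	0.7407	0.702	0.854	0.7449	0.8621	0.8991	0.7404	0.8856	0.7098	0.8554	0.7399	0.7957
chr1	11510	0.838	0.8521	0.7553	0.7588	0.785	0.8745	0.8804	0.7782	0.862	0.8866	0.8276	0.8951
chr1	11630	0.7273	0.8737	0.8353	0.8768	0.8434	0.863	0.8927	0.888	0.8952	0.7417	0.8223	0.7658
chr1	12320	0.739	0.8072	0.7277	0.869	0.7642	0.8212	0.7714	0.7908	0.8131	0.7863	0.8882	0.876
chr1	12330	0.817	0.8131	0.7024	0.8119	0.7904	0.7739	0.7194	0.7275	0.8837	0.7734	0.7353	0.7736
chr1	12450	0.8392	0.811	0.7018	0.8349	0.8597	0.7857	0.8872	0.7162	0.8708	0.7758	0.7266	0.846
chr1	12990	0.8283	0.8188	0.8363	0.8833	0.7448	0.739	0.85	0.7153	0.7556	0.8761	0.8349	0.7107
chr1	13800	0.708	0.8358	0.7045	0.7837	0.7165	0.7925	0.8686	0.8971	0.8296	0.8202	0.7833	0.7942
chr1	14030	0.7312	0.8319	0.843	0.7905	0.7222	0.7222	0.8627	0.8813	0.7882	0.8586	0.817	0.7667
chr1	15690	0.746	0.7915	0.7924	0.8777	0.7093	0.8814	0.703	0.7703	0.7079	0.8894	0.707	0.8417
chr1	16150	0.7354	0.8595	0.8369	0.8461	0.7009	0.7384	0.7006	0.7238	0.8494	0.7156	0.8636	0.7704
chr1	16780	0.8934	0.8692	0.7931	0.7327	0.8178	0.8806	0.8795	0.8537	0.839	0.7619	0.7164	0.8106
chr1	17070	0.8055	0.8244	0.8387	0.7834	0.8841	0.8909	0.7647	0.8738	0.8663	0.8823	0.8038	0.8827
chr1	17390	0.8449	0.8642	0.8663	0.7972	0.8552	0.7191	0.8236	0.7251	0.8212	0.7039	0.7316	0.738
chr1	18430	0.8348	0.7473	0.8773	0.8816	0.7976	0.739	0.7766	0.7036	0.7379	0.7154	0.8726	0.8435
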